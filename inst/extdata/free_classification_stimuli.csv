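# Six-stimulus free-classification set (synthetic reconstruction of the
# published figure, whose exact coordinates are available only graphically;
# override via the `stimuli` argument of free_classification_structure()).
# The layout instantiates the three critical bipartitions described with the
# figure: `os` = overall similarity (two compact blobs), `odsim` =
# one-dimensional similarity (near but inexact matches on dimension x),
# `odid` = one-dimensional identity (exact matches on dimension x).
# Columns: id, x, y, and the group (1/2) of each stimulus under each
# critical partition.
id,x,y,os,odsim,odid
1,0.0,0.0,1,1,1
2,0.0,0.2,1,1,1
3,1.0,0.1,1,2,2
4,1.0,1.0,2,1,2
5,0.0,1.5,2,2,1
6,1.0,1.4,2,2,2
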