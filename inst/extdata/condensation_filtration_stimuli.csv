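# Eight-stimulus ring for the condensation/filtration task, transcribed from
# the published category-structure figure (graphical transcription; unit grid:
# neighboring stimuli that differ on one dimension are one unit apart).
# Columns: id, x (dimension 1), y (dimension 2).
id,x,y
1,2,1
2,3,1
3,1,2
4,4,2
5,1,3
6,4,3
7,2,4
8,3,4
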