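# Default mitochondrial contamination screen (25 canonical
# mitochondrion-encoded genes).  Editable default; supply your own
# file to marker_set() to override.
cox1
cox2
cox3
cob
atp4
atp6
atp8
atp9
nad1
nad2
nad3
nad4
nad4L
nad5
nad6
nad7
nad9
nad11
rpl16
rps3
rps4
rps12
tatC
sdh3
sdh4
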