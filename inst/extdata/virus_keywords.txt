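capsid
phage
terminase
base plate
baseplate
prohead
virion
virus
viral
tape measure
tapemeasure
neck
tail
head
bacteriophage
prophage
portal
DNA packaging
T4
p22
holin
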