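prefix	class
bla	beta-lactam
tet	tetracycline
erm	macrolide
mef	macrolide
msr	macrolide
aph	aminoglycoside
aac	aminoglycoside
ant	aminoglycoside
aad	aminoglycoside
qnr	quinolone
oqx	quinolone
sul	sulphonamide
dfr	trimethoprim
van	glycopeptide
cat	phenicol
flo	phenicol
cfr	phenicol
mcr	colistin
fos	fosfomycin
lnu	lincosamide
vga	streptogramin
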