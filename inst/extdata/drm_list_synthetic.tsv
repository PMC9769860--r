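species	risk_group
Klebsiella pneumoniae	2
Escherichia coli	2
Salmonella enterica	2
Campylobacter jejuni	2
Vibrio fluvialis	2
Vibrio vulnificus	2
Vibrio parahaemolyticus	2
Clostridioides difficile	2
Clostridium perfringens	2
Enterococcus faecalis	2
Enterococcus faecium	2
Staphylococcus aureus	2
Streptococcus pyogenes	2
Shigella flexneri	2
Shigella sonnei	2
Yersinia enterocolitica	2
Listeria monocytogenes	2
Helicobacter pylori	2
Proteus mirabilis	3
Enterobacter cloacae	3
Citrobacter freundii	3
Aeromonas hydrophila	3
Pseudomonas aeruginosa	2
Acinetobacter baumannii	2
Bacteroides fragilis	3
Fusobacterium nucleatum	3
Haemophilus influenzae	2
Morganella morganii	3
Serratia marcescens	3
Providencia rettgeri	3
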