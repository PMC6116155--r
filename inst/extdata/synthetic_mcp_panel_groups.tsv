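protein_id	group_label
Gokushovirinae_ref1	Gokushovirinae
Gokushovirinae_ref2	Gokushovirinae
Group_D_ref1	Group_D
Group_D_ref2	Group_D
Pichovirinae_ref1	Pichovirinae
Pichovirinae_ref2	Pichovirinae
Alpavirinae_ref1	Alpavirinae
Alpavirinae_ref2	Alpavirinae
Parabacteroides_prophage_ref1	Parabacteroides_prophage
Parabacteroides_prophage_ref2	Parabacteroides_prophage
Pequenovirus_ref1	Pequenovirus
Pequenovirus_ref2	Pequenovirus
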