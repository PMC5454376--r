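name	start	end	category
beta1	32	39	strand
G-1/P-loop	40	47	G-box
alpha1	48	60	helix
helical-domain	63	175	domain
SwI	176	184	switch
G-2/SwI	176	184	G-box
SwII	199	219	switch
G-3	200	205	G-box
alpha3	220	232	helix
SwIII	233	245	switch
alpha3-beta5	246	254	loop
G-4	266	272	G-box
G-5	320	327	G-box
alpha5	329	350	helix
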