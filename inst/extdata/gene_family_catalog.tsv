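family_id	gene_symbol	role	domain_scope	strict_tier
TIGR00190	thiC	synthesis	both	TRUE
TIGR00097	thiD	synthesis	both	TRUE
B1HMM_thiDN	thiDN	synthesis	archaea	TRUE
TIGR00693	thiE	synthesis	bacteria	TRUE
PF05690	thiG	synthesis	bacteria	TRUE
PF01946	thi4	synthesis	both	TRUE
TIGR01379	thiL	synthesis	both	TRUE
B1HMM_thiN	thiN	synthesis	both	TRUE
B1HMM_thiK	thiK	salvage	bacteria	TRUE
TIGR00694	thiM	salvage	bacteria	TRUE
PF03070	tenA	salvage	both	TRUE
TIGR02357	thiT	transport	bacteria	TRUE
TIGR01254	thiB	transport	bacteria	TRUE
B1HMM_thiP	thiP	transport	bacteria	TRUE
B1HMM_thiQ	thiQ	transport	bacteria	TRUE
B1HMM_thiX	thiX	transport	bacteria	TRUE
B1HMM_thiY	thiY	transport	bacteria	TRUE
B1HMM_thiZ	thiZ	transport	bacteria	TRUE
B1HMM_cytX	cytX	transport	both	TRUE
B1HMM_ykoC	ykoC	transport	bacteria	TRUE
B1HMM_ykoD	ykoD	transport	bacteria	TRUE
B1HMM_ykoE	ykoE	transport	bacteria	TRUE
B1HMM_ykoF	ykoF	transport	bacteria	TRUE
B1HMM_omr1	omr1	transport	both	TRUE
K10944	amoA	chemoautotrophy	archaea	TRUE
K00371	nxr	chemoautotrophy	bacteria	TRUE
K00394	aprA	chemoautotrophy	bacteria	FALSE
K00395	aprB	chemoautotrophy	bacteria	FALSE
K11180	dsrA	chemoautotrophy	bacteria	FALSE
K01601	rbcL	chemoautotrophy	bacteria	TRUE
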