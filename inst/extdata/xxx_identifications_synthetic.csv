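sequence,score,sample,trypsin_caveat
LEHHHHHHEKP,16.8,GRO.DD_pUAG-GFP,FALSE
LEHHHHHHQLD,22.4,GRO.DD_pUAG-GFP,FALSE
LEHHHHHHQQR,31.0,GRO.DD_pUAG-GFP,TRUE
LEHHHHHHSLK,18.2,GRO.DD_pUAG-GFP,TRUE
LEHHHHHHYQR,27.5,GRO.DD_pUAG-GFP,TRUE
LEHHHHHHMVR,40.1,GRO.DD_pUAG-GFP,TRUE
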