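sequence,score,sample
LEHHHHHH,45.2,GRO.DD_pUAG-GFP
LEHHHHHHQGAR,52.1,GRO.DD_pUAG-GFP
LEHHHHHHYGAR,38.7,GRO.DD_pUAG-GFP
LEHHHHHHDGAR,21.4,GRO.DD_pUAG-GFP
LEHHHHHHVGAR,19.9,GRO.DD_pUAG-GFP
LEHHHHHHH,41.3,GRO.DD_pUAG-GFP
LEHHHHHHHH,24.6,GRO.DD_pUAG-GFP
LEHHHHHHGDPMVR,47.8,GRO.DD_pUAG-GFP
LEHHHHHHMVR,35.5,GRO.DD_pUAG-GFP
ALGDPMVR,58.3,GRO.DD_pUAG-GFP
SVIPWFVK,17.6,GRO.DD_pUAG-GFP
INGINSTGR,29.4,GRO.DD_pUAG-GFP
LEHHHHHHAANDENYALDD,61.0,GRO.DD_pUAG-GFP
LEHHHHHHGDAANDENYALDD,33.2,GRO.DD_pUAG-GFP
LLGGAVFK,7.2,GRO.DD_pUAG-GFP
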