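name	lox_sites	flexible
1L66	lox66	FALSE
1L71	lox71	FALSE
1WL1	loxP	FALSE
1WL2	loxP	TRUE
2ML1	lox511/71,loxFAS/66	FALSE
2ML4	lox511/71,loxFAS/66	TRUE
2ML5	lox71,loxm2/66	TRUE
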