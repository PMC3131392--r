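terminal_a,terminal_b,island
batakorum_Palawan,palawanensis_GreaterPalawan,Palawan
grandis_Mindanao,beatus_GreaterMindanao,Mindanao
grayi_Mindoro,mindorus_Mindoro,Mindoro
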