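terminal,species,island,mean_mm,se_mm,n
batakorum_Palawan,Crocidura batakorum,Palawan,18.01,0.091,5
beatus_GreaterMindanao,Crocidura beatus,Greater Mindanao,20.99,0.143,13
beatus_Camiguin,Crocidura beatus,Camiguin,20.80,0.136,6
grandis_Mindanao,Crocidura grandis,Mindanao,23.70,,1
grayi_Luzon,Crocidura grayi,Luzon,20.12,0.091,23
grayi_Calayan,Crocidura grayi,Calayan,21.17,0.170,4
grayi_Mindoro,Crocidura grayi,Mindoro,19.63,0.032,15
mindorus_Mindoro,Crocidura mindorus,Mindoro,22.28,0.141,4
negrina_Negros,Crocidura negrina,Negros,22.93,0.215,8
palawanensis_GreaterPalawan,Crocidura palawanensis,Greater Palawan,23.62,0.145,27
panayensis_Panay,Crocidura panayensis,Panay,21.45,0.279,7
ninoyi_Sibuyan,Crocidura ninoyi,Sibuyan,22.60,0.335,3
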