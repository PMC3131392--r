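species,island,area_km2,paic
Crocidura batakorum,Palawan,11785,Palawan
Crocidura beatus,Biliran,498,Mindanao
Crocidura beatus,Bohol,3864,Mindanao
Crocidura beatus,Camiguin Sur,249,
Crocidura beatus,Leyte,7213,Mindanao
Crocidura beatus,Maripipi,22,Mindanao
Crocidura beatus,Mindanao,96467,Mindanao
Crocidura beatus,Samar,13429,Mindanao
Crocidura grandis,Mindanao,96467,Mindanao
Crocidura grayi,Calayan,196,
Crocidura grayi,Catanduanes,1513,Luzon
Crocidura grayi,Luzon,107170,Luzon
Crocidura grayi,Mindoro,9735,Mindoro
Crocidura mindorus,Mindoro,9735,Mindoro
Crocidura negrina,Negros,13670,Negros-Panay
Crocidura ninoyi,Sibuyan,449,
Crocidura palawanensis,Balabac,306,Palawan
Crocidura palawanensis,Palawan,11785,Palawan
Crocidura panayensis,Panay,12300,Negros-Panay
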