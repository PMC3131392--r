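unit,Luzon,Mindanao,Mindoro,Negros-Panay,Palawan,Sulu
Luzon,0,24,15,31,270,410
Mindanao,24,0,95,38,330,120
Mindoro,15,95,0,45,150,360
Negros-Panay,31,38,45,0,210,200
Palawan,270,330,150,210,0,290
Sulu,410,120,360,200,290,0
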