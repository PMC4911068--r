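species,sex,body_mass_kg,l0_mm,stress_A_kPa,stress_B,fo1_hz,fo2_hz,source
Greater horseshoe bat,unspecified,0.02,1,,,2000,80000,literature
House mouse,unspecified,0.05,1,,,1000,9000,pers. observation
Laboratory rat,male,0.4,2,0.5,4.4,500,6000,literature
Guinea pig,unspecified,0.8,2,,,250,4000,literature
Human,male,75,16,4,9.4,90,450,literature
Human,female,60,10,5.5,7.6,120,800,literature
Rhesus monkey,male,6.4,8.3,1.1,16.2,100,1800,literature
Rhesus monkey,female,5.1,7.8,2.5,12.9,100,1800,literature
Raccoon,unspecified,5,4,,,200,4000,literature
Domestic dog,unspecified,10,8,,,60,1500,literature
Rocky Mountain elk,male,250,31,3.3,6.5,100,2400,literature
Rocky Mountain elk,female,150,29,3.1,5.9,100,2400,literature
Mule deer,male,80,24,3.8,8.2,,,literature
Mule deer,female,65,21,2.9,7.9,,,literature
Grevy's zebra,unspecified,200,29,,,,,literature
Domestic cow,unspecified,400,35,,,,,literature
African lion,male,250,38,0.7,8,20,250,literature
Siberian tiger,male,300,40,0.8,8.5,20,250,literature
Giraffe,unspecified,1000,40,,,,,pers. observation
African elephant,unspecified,5000,100,,,,,literature
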