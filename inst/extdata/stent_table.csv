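stent_no,diameter_mm,length_mm,product_name,manufacturer,covered
1,3.0,24.0,Promus ELITE MONORAIL,Boston Scientific,FALSE
2,3.0,26.0,Synsiro,Biotronik,FALSE
3,3.0,15.0,PK Papyrus,Biotronik,TRUE
4,3.5,26.0,PK Papyrus,Biotronik,TRUE
5,3.5,38.0,Resolute Onyx,Medtronic,FALSE
6,4.0,26.0,Resolute Onyx,Medtronic,FALSE
7,4.0,15.0,PK Papyrus,Biotronik,TRUE
8,4.5,18.0,Resolute Onyx,Medtronic,FALSE
9,5.0,27.0,Visi-Pro,Ev3,FALSE
10,6.2,30.0,ASSURAND Cobald,Medtronic,FALSE
11,7.9,30.0,ASSURAND Cobald,Medtronic,FALSE
12,8.0,100.0,Supera Vertias System,Supera Veritas,FALSE
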