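lead_id,x,y
C3,0,0
E002,1,0
E003,0.5,0.866025403784439
E004,-0.5,0.866025403784439
E005,-1,0
E006,-0.5,-0.866025403784439
E007,0.5,-0.866025403784439
E008,2,0
E009,1.5,0.866025403784439
E010,1,1.73205080756888
E011,0,1.73205080756888
E012,-1,1.73205080756888
E013,-1.5,0.866025403784439
E014,-2,0
E015,-1.5,-0.866025403784439
E016,-1,-1.73205080756888
E017,0,-1.73205080756888
E018,1,-1.73205080756888
E019,1.5,-0.866025403784439
E020,3,0
E021,2.5,0.866025403784439
E022,2,1.73205080756888
E023,1.5,2.59807621135332
E024,0.5,2.59807621135332
E025,-0.5,2.59807621135332
E026,-1.5,2.59807621135332
E027,-2,1.73205080756888
E028,-2.5,0.866025403784439
E029,-3,0
E030,-2.5,-0.866025403784439
E031,-2,-1.73205080756888
E032,-1.5,-2.59807621135332
E033,-0.5,-2.59807621135332
E034,0.5,-2.59807621135332
E035,1.5,-2.59807621135332
E036,2,-1.73205080756888
E037,2.5,-0.866025403784439
E038,4,0
E039,3.5,0.866025403784439
E040,3,1.73205080756888
E041,2.5,2.59807621135332
E042,2,3.46410161513775
E043,1,3.46410161513775
E044,0,3.46410161513775
E045,-1,3.46410161513775
E046,-2,3.46410161513775
E047,-2.5,2.59807621135332
E048,-3,1.73205080756888
E049,-3.5,0.866025403784439
E050,-4,0
E051,-3.5,-0.866025403784439
E052,-3,-1.73205080756888
E053,-2.5,-2.59807621135332
E054,-2,-3.46410161513775
E055,-1,-3.46410161513775
E056,0,-3.46410161513775
E057,1,-3.46410161513775
E058,2,-3.46410161513775
E059,2.5,-2.59807621135332
E060,3,-1.73205080756888
E061,3.5,-0.866025403784439
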