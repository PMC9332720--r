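"disease_id","sex","age_start","rate"
"d_cvd","male",0,2.86939415502762e-05
"d_cvd","male",1,3.54876945740045e-05
"d_cvd","male",5,5.20230039635287e-05
"d_cvd","male",10,7.95738884647234e-05
"d_cvd","male",15,0.000121715457451003
"d_cvd","male",20,0.000186174797642
"d_cvd","male",25,0.000284771186855972
"d_cvd","male",30,0.000435583279211064
"d_cvd","male",35,0.000666264010846802
"d_cvd","male",40,0.00101911104795777
"d_cvd","male",45,0.00155882249552931
"d_cvd","male",50,0.00238435995511739
"d_cvd","male",55,0.00364709414437656
"d_cvd","male",60,0.00557856026284879
"d_cvd","male",65,0.00853291233356833
"d_cvd","male",70,0.0130518609572536
"d_cvd","male",75,0.0199640014789936
"d_cvd","male",80,0.0305367454004141
"d_cvd","male",85,0.0467087132121732
"d_cvd","male",90,0.0714452002441444
"d_cvd","male",95,0.109281893824375
"d_cancer","male",0,1.72163649301657e-05
"d_cancer","male",1,2.12926167444027e-05
"d_cancer","male",5,3.12138023781172e-05
"d_cancer","male",10,4.77443330788341e-05
"d_cancer","male",15,7.30292744706019e-05
"d_cancer","male",20,0.0001117048785852
"d_cancer","male",25,0.000170862712113583
"d_cancer","male",30,0.000261349967526638
"d_cancer","male",35,0.000399758406508081
"d_cancer","male",40,0.00061146662877466
"d_cancer","male",45,0.000935293497317583
"d_cancer","male",50,0.00143061597307043
"d_cancer","male",55,0.00218825648662593
"d_cancer","male",60,0.00334713615770927
"d_cancer","male",65,0.005119747400141
"d_cancer","male",70,0.00783111657435216
"d_cancer","male",75,0.0119784008873962
"d_cancer","male",80,0.0183220472402485
"d_cancer","male",85,0.0280252279273039
"d_cancer","male",90,0.0428671201464866
"d_cancer","male",95,0.065569136294625
"resid","male",0,1.14775766201105e-05
"resid","male",1,1.41950778296018e-05
"resid","male",5,2.08092015854115e-05
"resid","male",10,3.18295553858894e-05
"resid","male",15,4.86861829804013e-05
"resid","male",20,7.44699190568001e-05
"resid","male",25,0.000113908474742389
"resid","male",30,0.000174233311684426
"resid","male",35,0.000266505604338721
"resid","male",40,0.000407644419183106
"resid","male",45,0.000623528998211722
"resid","male",50,0.000953743982046954
"resid","male",55,0.00145883765775062
"resid","male",60,0.00223142410513951
"resid","male",65,0.00341316493342733
"resid","male",70,0.00522074438290144
"resid","male",75,0.00798560059159744
"resid","male",80,0.0122146981601656
"resid","male",85,0.0186834852848693
"resid","male",90,0.0285780800976578
"resid","male",95,0.04371275752975
"d_cvd","female",0,2.39985692965946e-05
"d_cvd","female",1,2.96806172800765e-05
"d_cvd","female",5,4.35101487694967e-05
"d_cvd","female",10,6.65527067159505e-05
"d_cvd","female",15,0.000101798382595385
"d_cvd","female",20,0.000155709830755127
"d_cvd","female",25,0.000238172265370449
"d_cvd","female",30,0.000364306015340163
"d_cvd","female",35,0.000557238990890053
"d_cvd","female",40,0.000852347421928314
"d_cvd","female",45,0.00130374245080633
"d_cvd","female",50,0.00199419196246181
"d_cvd","female",55,0.0030502969207513
"d_cvd","female",60,0.00466570494710989
"d_cvd","female",65,0.00713661758807533
"d_cvd","female",70,0.0109161018915212
"d_cvd","female",75,0.0166971648733401
"d_cvd","female",80,0.0255398234258009
"d_cvd","female",85,0.0390654692319994
"d_cvd","female",90,0.0597541674769208
"d_cvd","female",95,0.0913994021076591
"d_cancer","female",0,1.43991415779568e-05
"d_cancer","female",1,1.78083703680459e-05
"d_cancer","female",5,2.6106089261698e-05
"d_cancer","female",10,3.99316240295703e-05
"d_cancer","female",15,6.10790295572307e-05
"d_cancer","female",20,9.34258984530764e-05
"d_cancer","female",25,0.000142903359222269
"d_cancer","female",30,0.000218583609204098
"d_cancer","female",35,0.000334343394534032
"d_cancer","female",40,0.000511408453156988
"d_cancer","female",45,0.000782245470483797
"d_cancer","female",50,0.00119651517747709
"d_cancer","female",55,0.00183017815245078
"d_cancer","female",60,0.00279942296826594
"d_cancer","female",65,0.0042819705528452
"d_cancer","female",70,0.00654966113491271
"d_cancer","female",75,0.0100182989240041
"d_cancer","female",80,0.0153238940554805
"d_cancer","female",85,0.0234392815391996
"d_cancer","female",90,0.0358525004861525
"d_cancer","female",95,0.0548396412645955
"resid","female",0,9.59942771863784e-06
"resid","female",1,1.18722469120306e-05
"resid","female",5,1.74040595077987e-05
"resid","female",10,2.66210826863802e-05
"resid","female",15,4.07193530381538e-05
"resid","female",20,6.2283932302051e-05
"resid","female",25,9.52689061481796e-05
"resid","female",30,0.000145722406136065
"resid","female",35,0.000222895596356021
"resid","female",40,0.000340938968771325
"resid","female",45,0.000521496980322531
"resid","female",50,0.000797676784984725
"resid","female",55,0.00122011876830052
"resid","female",60,0.00186628197884396
"resid","female",65,0.00285464703523013
"resid","female",70,0.00436644075660848
"resid","female",75,0.00667886594933604
"resid","female",80,0.0102159293703204
"resid","female",85,0.0156261876927998
"resid","female",90,0.0239016669907683
"resid","female",95,0.0365597608430637
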