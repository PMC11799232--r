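drug,section,level,count,percent
voriconazole,sex,female,2857,32.11
voriconazole,sex,male,4477,50.31
voriconazole,sex,unknown,1564,17.58
voriconazole,age,<18,586,6.59
voriconazole,age,18-44,986,11.08
voriconazole,age,45-64,2067,23.23
voriconazole,age,>=65,2624,29.49
voriconazole,age,unknown,2635,29.61
voriconazole,country,USA,3904,43.88
voriconazole,country,JPN,968,10.88
voriconazole,country,FR,697,7.83
voriconazole,country,CN,640,7.19
voriconazole,country,UK,349,3.92
posaconazole,sex,female,640,32.85
posaconazole,sex,male,914,46.92
posaconazole,sex,unknown,394,20.23
posaconazole,age,<18,152,7.80
posaconazole,age,18-44,278,14.27
posaconazole,age,45-64,437,22.43
posaconazole,age,>=65,312,16.02
posaconazole,age,unknown,769,39.48
posaconazole,country,USA,1052,54.00
posaconazole,country,FR,167,8.57
posaconazole,country,UK,98,5.03
posaconazole,country,DE,89,4.57
posaconazole,country,CN,64,3.29
isavuconazole,sex,female,296,31.36
isavuconazole,sex,male,553,58.58
isavuconazole,sex,unknown,95,10.06
isavuconazole,age,<18,38,4.03
isavuconazole,age,18-44,117,12.39
isavuconazole,age,45-64,315,33.37
isavuconazole,age,>=65,222,23.52
isavuconazole,age,unknown,252,26.69
isavuconazole,country,USA,416,44.07
isavuconazole,country,CN,134,14.19
isavuconazole,country,ES,81,8.58
isavuconazole,country,UK,71,7.52
isavuconazole,country,FR,66,6.99
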