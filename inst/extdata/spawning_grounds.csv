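index,name,lon,lat,radius_km
1,Buagrunnen,6.9,63.00,10
2,Froeyabanken,8.3,63.80,10
3,Haltenbanken,9.2,64.50,12
4,Vikna,10.46,65.03,8
5,Sklinnabanken,10.7,65.45,10
6,Traenabanken,12.0,66.50,12
7,Roest,12.0,67.45,12
8,Moskenesgrunnen,12.7,67.90,12
9,Vestfjorden,13.73,68.40,10
10,Vesteraalen,14.8,68.90,10
11,Senja,16.6,69.48,10
12,Malangsgrunnen,17.56,69.73,10
13,Nordvestbanken,20.77,70.26,10
14,Soeroeya,22.72,70.46,10
15,Nordkappbanken,26.29,70.76,12
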