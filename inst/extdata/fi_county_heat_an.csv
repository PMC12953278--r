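region_id,scenario,an_2010_2019,an_2050_2059,an_2090_2099,ratio_printed
Central Uusimaa,SSP2-4.5,22,48,76,3.4
West Uusimaa,SSP2-4.5,-21,-64,-113,NA
Vantaa & Kerava,SSP2-4.5,119,245,378,3.2
Helsinki,SSP2-4.5,107,315,540,5.0
Kymenlaakso,SSP2-4.5,107,204,313,2.9
Paijat-Hame,SSP2-4.5,47,88,131,2.8
South Karelia,SSP2-4.5,172,306,457,2.7
Pirkanmaa,SSP2-4.5,54,125,202,3.7
South Ostrobothnia,SSP2-4.5,-120,-194,-277,NA
Kanta-Hame,SSP2-4.5,30,54,79,2.6
Satakunta,SSP2-4.5,130,214,301,2.3
Southwest Finland,SSP2-4.5,28,67,107,3.8
Ostrobothnia,SSP2-4.5,34,91,156,4.6
South Savo,SSP2-4.5,-130,-163,-190,NA
Central Finland,SSP2-4.5,-29,-57,-90,NA
North Karelia,SSP2-4.5,178,309,485,2.7
North Savo,SSP2-4.5,87,171,284,3.5
North Ostrobothnia,SSP2-4.5,40,70,111,2.8
Lapland,SSP2-4.5,-9,-20,-38,NA
Central Uusimaa,SSP5-8.5,25,70,201,8.0
West Uusimaa,SSP5-8.5,-26,-102,-350,NA
Vantaa & Kerava,SSP5-8.5,136,343,905,6.6
Helsinki,SSP5-8.5,136,497,1577,11.6
Kymenlaakso,SSP5-8.5,117,279,718,6.1
Paijat-Hame,SSP5-8.5,52,120,300,5.7
South Karelia,SSP5-8.5,184,408,993,5.4
Pirkanmaa,SSP5-8.5,62,186,532,8.5
South Ostrobothnia,SSP5-8.5,-128,-243,-501,NA
Kanta-Hame,SSP5-8.5,32,72,174,5.4
Satakunta,SSP5-8.5,139,266,562,4.0
Southwest Finland,SSP5-8.5,33,96,276,8.4
Ostrobothnia,SSP5-8.5,41,133,388,9.5
South Savo,SSP5-8.5,-131,-171,-174,NA
Central Finland,SSP5-8.5,-33,-72,-222,NA
North Karelia,SSP5-8.5,193,428,1098,5.7
North Savo,SSP5-8.5,100,256,721,7.2
North Ostrobothnia,SSP5-8.5,45,97,245,5.4
Lapland,SSP5-8.5,-11,-31,-103,NA
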