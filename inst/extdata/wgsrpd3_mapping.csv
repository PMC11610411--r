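botanical_country,political_country,alias
Borneo,Brunei,
Borneo,Indonesia,
Borneo,Malaysia,
Peru,Peru,
Madagascar,Madagascar,
Brazil North,Brazil,
Brazil Northeast,Brazil,
Brazil West-Central,Brazil,
Brazil Southeast,Brazil,
Brazil South,Brazil,
Mexico Central,Mexico,
Mexico Gulf,Mexico,
Mexico Northeast,Mexico,
Mexico Northwest,Mexico,
Mexico Southeast,Mexico,
Mexico Southwest,Mexico,
Colombia,Colombia,
Ecuador,Ecuador,
Bolivia,Bolivia,
Venezuela,Venezuela,
Guyana,Guyana,
Suriname,Suriname,
French Guiana,France,
Argentina Northeast,Argentina,
Argentina Northwest,Argentina,
Argentina South,Argentina,
Chile Central,Chile,
Chile North,Chile,
Chile South,Chile,
New Guinea,Indonesia,
New Guinea,Papua New Guinea,
Sumatera,Indonesia,
Jawa,Indonesia,
Sulawesi,Indonesia,
Maluku,Indonesia,
Lesser Sunda Is.,Indonesia,
Lesser Sunda Is.,Timor-Leste,
Malaya,Malaysia,
Malaya,Singapore,
Thailand,Thailand,
Myanmar,Myanmar,Burma
Vietnam,Vietnam,
Cambodia,Cambodia,
Laos,Laos,
India,India,
Sri Lanka,Sri Lanka,
Nepal,Nepal,
China North-Central,China,
China South-Central,China,
China Southeast,China,
Tibet,China,
Hainan,China,
Taiwan,Taiwan,
Japan,Japan,
Korea,North Korea,
Korea,South Korea,
Queensland,Australia,
New South Wales,Australia,
Northern Territory,Australia,
Western Australia,Australia,
Tasmania,Australia,
New Zealand North,New Zealand,
New Zealand South,New Zealand,
Cape Provinces,South Africa,
KwaZulu-Natal,South Africa,
Tanzania,Tanzania,
Kenya,Kenya,
Ethiopia,Ethiopia,
Cameroon,Cameroon,
Gabon,Gabon,
Zaire,Democratic Republic of the Congo,Congo-Kinshasa
Ivory Coast,Ivory Coast,Côte d'Ivoire
Spain,Spain,
Portugal,Portugal,
France,France,
Corse,France,Corsica
Italy,Italy,
Sicilia,Italy,Sicily
Greece,Greece,
Turkey,Turkey,
Great Britain,United Kingdom,
Ireland,Ireland,
Ireland,United Kingdom,
Norway,Norway,
Sweden,Sweden,
Finland,Finland,
Alaska,United States,
California,United States,
Texas,United States,
Florida,United States,
Ontario,Canada,
Québec,Canada,Quebec
Cuba,Cuba,
Jamaica,Jamaica,
Haiti,Haiti,
Dominican Republic,Dominican Republic,
Panamá,Panama,Panama
Costa Rica,Costa Rica,
Nicaragua,Nicaragua,
Guatemala,Guatemala,
Belize,Belize,
Honduras,Honduras,
El Salvador,El Salvador,
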