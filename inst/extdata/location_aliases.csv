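alias,iso3
Viet Nam,VNM
Vietnam,VNM
United States,USA
United States of America,USA
Russia,RUS
Russian Federation,RUS
Iran,IRN
"Iran, Islamic Rep.",IRN
Iran (Islamic Republic of),IRN
South Korea,KOR
"Korea, Rep.",KOR
Republic of Korea,KOR
North Korea,PRK
"Korea, Dem. People's Rep.",PRK
Democratic People's Republic of Korea,PRK
"Egypt, Arab Rep.",EGY
Egypt,EGY
Turkey,TUR
Turkiye,TUR
Czechia,CZE
Czech Republic,CZE
Laos,LAO
Lao PDR,LAO
Lao People's Democratic Republic,LAO
Syria,SYR
Syrian Arab Republic,SYR
"Venezuela, RB",VEN
Venezuela (Bolivarian Republic of),VEN
Bolivia,BOL
Bolivia (Plurinational State of),BOL
Tanzania,TZA
United Republic of Tanzania,TZA
"Congo, Dem. Rep.",COD
Democratic Republic of the Congo,COD
"Congo, Rep.",COG
Congo,COG
Moldova,MDA
Republic of Moldova,MDA
Brunei,BRN
Brunei Darussalam,BRN
Cape Verde,CPV
Cabo Verde,CPV
Swaziland,SWZ
Eswatini,SWZ
"Micronesia, Fed. Sts.",FSM
Micronesia (Federated States of),FSM
Slovak Republic,SVK
Slovakia,SVK
Kyrgyz Republic,KGZ
Kyrgyzstan,KGZ
"Gambia, The",GMB
Gambia,GMB
"Bahamas, The",BHS
Bahamas,BHS
Saint Lucia,LCA
St. Lucia,LCA
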