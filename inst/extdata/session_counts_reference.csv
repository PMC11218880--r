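variable,level,n_rar,n_no_rar
photo,No,854,2840564
photo,Yes,90,573262
sex,Female,445,1619408
sex,Male,499,1794367
sex,Unknown,0,51
race,White,433,1605254
race,Black,471,1555859
race,Asian,33,129776
race,Other,8,21552
ethnicity,Hispanic,109,508928
ethnicity,Non-Hispanic,833,2896028
care_group,Cardiac,153,360713
care_group,GeneralCare,216,991455
care_group,ICU,379,941701
care_group,Other,196,1119957
shift,Day,666,2501458
shift,Night,278,912368
provider_type,Attending,353,1464390
provider_type,Fellow,78,255723
provider_type,Resident,210,646791
provider_type,PA/NP,260,879300
provider_type,Other,43,167622
insurance,Public,610,2098523
insurance,Private,329,1261255
insurance,SelfPay,5,54046
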