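concept_id,source_code,source_vocabulary,domain
2000001,I10,ICD10GM,Condition
2000002,E11.9,ICD10GM,Condition
2000003,J44.9,ICD10GM,Condition
2000004,C34.9,ICD10GM,Condition
2000005,I25.1,ICD10GM,Condition
2000006,K52.9,ICD10GM,Condition
2000007,N18.9,ICD10GM,Condition
2000008,F32.9,ICD10GM,Condition
2000009,M54.5,ICD10GM,Condition
2000010,A09.0,ICD10GM,Condition
2000011,C50.9,ICD10GM,Condition
2000012,G40.9,ICD10GM,Condition
2000013,Z01.7,ICD10GM,Observation
2000014,Z92.1,ICD10GM,Observation
2000015,R94.5,ICD10GM,Measurement
2000016,Z51.5,ICD10GM,Procedure
2000017,U69.0,ICD10GM,Observation
2000101,718-7,LOINC,Measurement
2000102,2160-0,LOINC,Measurement
2000103,2951-2,LOINC,Measurement
2000104,6690-2,LOINC,Measurement
2000105,17861-6,LOINC,Measurement
2000106,2093-3,LOINC,Measurement
2000107,8867-4,LOINC,Measurement
2000108,8480-6,LOINC,Measurement
2000109,72166-2,LOINC,Observation
2000110,29463-7,LOINC,Measurement
2000111,8302-2,LOINC,Measurement
2000112,74013-4,LOINC,Observation
2000113,10160-0,LOINC,Observation
2000201,5-470,OPS,Procedure
2000202,1-632,OPS,Procedure
2000203,8-800,OPS,Procedure
2000204,5-511,OPS,Procedure
2000205,1-440,OPS,Procedure
2000206,8-930,OPS,Procedure
2000207,3-200,OPS,Procedure
2000208,5-032,OPS,Procedure
2000209,9-984,OPS,Observation
2000210,8-550,OPS,Procedure
2000301,N02BE01,ATC,Drug
2000302,A10BA02,ATC,Drug
2000303,C09AA02,ATC,Drug
2000304,B01AC06,ATC,Drug
2000305,J01CA04,ATC,Drug
2000306,C07AB07,ATC,Drug
2000307,A02BC01,ATC,Drug
2000308,R03AC02,ATC,Drug
2000309,N05BA06,ATC,Drug
2000310,M01AE01,ATC,Drug
2000401,261650005,TNM,Observation
2000402,258215001,TNM,Observation
2000403,258219007,TNM,Observation
2000404,261651009,TNM,Observation
2000405,24484000,SEVERITY,Observation
2000406,6736007,SEVERITY,Observation
2000407,255604002,SEVERITY,Observation
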