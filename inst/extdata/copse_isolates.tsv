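sample_id	rotu	region1	region2	region3	region4	order	feeding_code
SnTUT_z01_01	Z01rOTU16	R1_SV_19	R2_SV_17	R3_SV_16	R4_SV_24	Triplonchida	3
SnTUT_z01_02	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_03	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_04	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_06	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_07	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_09	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_10	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_15	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_16	Z01rOTU11	R1_SV_23	R2_SV_13	R3_SV_11	R4_SV_23	Rhabditida	1b
SnTUT_z01_18	Z01rOTU12	R1_SV_25	R2_SV_18	R3_SV_14	R4_SV_19	Triplonchida	3?
SnTUT_z01_19	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_20	Z01rOTU10	R1_SV_9	R2_SV_27	R3_SV_9	R4_SV_15	Rhabditida	3
SnTUT_z01_22	Z01rOTU11	R1_SV_23	R2_SV_13	R3_SV_11	R4_SV_23	Rhabditida	1b
SnTUT_z01_24	Z01rOTU12	R1_SV_25	R2_SV_18	R3_SV_14	R4_SV_19	Triplonchida	3?
SnTUT_z01_25	Z01rOTU18	R1_SV_27	R2_SV_20	R3_SV_17	R4_SV_29	Triplonchida	3
SnTUT_z01_27	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_28	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_30	Z01rOTU05	R1_SV_6	R2_SV_5	R3_SV_6	R4_SV_5	Triplonchida	1d
SnTUT_z01_31	Z01rOTU09	R1_SV_8	R2_SV_8	NA	R4_SV_13	Triplonchida	3
SnTUT_z01_33	Z01rOTU05	R1_SV_6	R2_SV_5	R3_SV_6	R4_SV_5	Triplonchida	1d
SnTUT_z01_34	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_35	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_36	Z01rOTU04	R1_SV_4	R2_SV_6	R3_SV_2	R4_SV_6	Dorylaimida	5
SnTUT_z01_37	Z01rOTU04	R1_SV_4	R2_SV_6	R3_SV_2	R4_SV_6	Dorylaimida	5
SnTUT_z01_40	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_41	Z01rOTU08	R1_SV_7	R2_SV_9	R3_SV_2	R4_SV_12	Dorylaimida	5
SnTUT_z01_42	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_43	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_44	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_45	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_46	Z01rOTU04	R1_SV_4	R2_SV_6	R3_SV_2	R4_SV_6	Dorylaimida	5
SnTUT_z01_47	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_49	Z01rOTU13	R1_SV_15	R2_SV_15	R3_SV_2	R4_SV_21	Dorylaimida	8?
SnTUT_z01_50	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_51	Z01rOTU08	R1_SV_7	R2_SV_9	R3_SV_2	R4_SV_12	Dorylaimida	5
SnTUT_z01_52	Z01rOTU15	R1_SV_18	R2_SV_16	R3_SV_12	R4_SV_22	Plectida	3
SnTUT_z01_53	Z01rOTU04	R1_SV_4	R2_SV_6	R3_SV_2	R4_SV_6	Dorylaimida	5
SnTUT_z01_56	Z01rOTU17	R1_SV_20	R2_SV_19	R3_SV_15	R4_SV_25	Triplonchida	3?
SnTUT_z01_57	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_59	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_61	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_63	Z01rOTU04	R1_SV_4	R2_SV_6	R3_SV_2	R4_SV_6	Dorylaimida	5
SnTUT_z01_67	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_68	Z01rOTU14	R1_SV_16	R2_SV_14	R3_SV_13	R4_SV_18	Triplonchida	2
SnTUT_z01_69	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_70	Z01rOTU05	R1_SV_6	R2_SV_5	R3_SV_6	R4_SV_5	Triplonchida	1d
SnTUT_z01_71	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_72	Z01rOTU07	R1_SV_11	R2_SV_10	R3_SV_8	R4_SV_10	Dorylaimida	2
SnTUT_z01_73	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_74	Z01rOTU04	R1_SV_4	R2_SV_6	R3_SV_2	R4_SV_6	Dorylaimida	5
SnTUT_z01_75	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_76	Z01rOTU09	R1_SV_8	R2_SV_8	NA	R4_SV_13	Triplonchida	3
SnTUT_z01_77	Z01rOTU01	R1_SV_2	R2_SV_2	R3_SV_4	R4_SV_1	Rhabditida	1d
SnTUT_z01_78	Z01rOTU04	R1_SV_4	R2_SV_6	R3_SV_2	R4_SV_6	Dorylaimida	5
SnTUT_z01_80	Z01rOTU05	R1_SV_6	R2_SV_5	R3_SV_6	R4_SV_5	Triplonchida	1d
SnTUT_z01_82	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_83	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_84	Z01rOTU02	R1_SV_3	R2_SV_3	R3_SV_3	R4_SV_3	Dorylaimida	2
SnTUT_z01_85	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_87	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_88	Z01rOTU10	R1_SV_9	R2_SV_27	R3_SV_9	R4_SV_15	Rhabditida	3
SnTUT_z01_89	Z01rOTU06	R1_SV_10	R2_SV_7	R3_SV_7	R4_SV_8	Rhabditida	1e
SnTUT_z01_91	Z01rOTU07	R1_SV_11	R2_SV_10	R3_SV_8	R4_SV_10	Dorylaimida	2
SnTUT_z01_93	Z01rOTU03	R1_SV_1	R2_SV_1	R3_SV_1	R4_SV_2	Dorylaimida	2
SnTUT_z01_94	Z01rOTU06	R1_SV_10	R2_SV_7	R3_SV_7	R4_SV_8	Rhabditida	1e
SnTUT_z01_95	Z01rOTU07	R1_SV_11	R2_SV_10	R3_SV_8	R4_SV_10	Dorylaimida	2
SnTUT_z01_96	Z01rOTU06	R1_SV_10	R2_SV_7	R3_SV_7	R4_SV_8	Rhabditida	1e
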