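compound,coupling,value
5a,"3J(H1,H2)",4.2
5b,"3J(H1,H2)",8.7
6a,"3J(H1,H2)",1.8
6b,"3J(H1,H2)",1.0
7a,"3J(H1,H2)",3.6
7b,"3J(H1,H2)",8.5
8a,"3J(H1,H2)",7.6
8b,"3J(H1,H2)",2.0
5a,"3J(H2,H3)",nd
5b,"3J(H2,H3)",8.7
6a,"3J(H2,H3)",3.4
6b,"3J(H2,H3)",3.2
7a,"3J(H2,H3)",6.8
7b,"3J(H2,H3)",8.7
8a,"3J(H2,H3)",3.2
8b,"3J(H2,H3)",3.4
5a,"3J(H3,H4)",nd
5b,"3J(H3,H4)",8.7
6a,"3J(H3,H4)",9.3
6b,"3J(H3,H4)",9.3
7a,"3J(H3,H4)",6.8
7b,"3J(H3,H4)",8.9
8a,"3J(H3,H4)",4.8
8b,"3J(H3,H4)",8.3
5a,"3J(H4,H5)",nd
5b,"3J(H4,H5)",9.6
6a,"3J(H4,H5)",nd
6b,"3J(H4,H5)",9.3
7a,"3J(H4,H5)",4.0
7b,"3J(H4,H5)",5.3
8a,"3J(H4,H5)",2.2
8b,"3J(H4,H5)",4.7
7a,"3J(H4,H5')",7.1
7b,"3J(H4,H5')",10.4
8a,"3J(H4,H5')",3.3
8b,"3J(H4,H5')",8.7
5a,"3J(H5,H6)",3.2
5b,"3J(H5,H6)",2.3
6a,"3J(H5,H6)",4.7
6b,"3J(H5,H6)",2.5
5a,"3J(H5,H6')",4.2
5b,"3J(H5,H6')",5.2
6a,"3J(H5,H6')",3.0
6b,"3J(H5,H6')",5.5
7a,"2J(H5,H5')",11.7
7b,"2J(H5,H5')",11.3
8a,"2J(H5,H5')",12.1
8b,"2J(H5,H5')",11.5
5a,"2J(H6,H6')",11.9
5b,"2J(H6,H6')",12.0
6a,"2J(H6,H6')",11.7
6b,"2J(H6,H6')",11.9
5a,"4J(H3,H5)",0
5b,"4J(H3,H5)",0
6a,"4J(H3,H5)",0
6b,"4J(H3,H5)",0
7a,"4J(H3,H5)",0
7b,"4J(H3,H5)",0
8a,"4J(H3,H5)",1.0
8b,"4J(H3,H5)",0
5a,"3J(NH,H1)",3.4
5b,"3J(NH,H1)",8.5
6a,"3J(NH,H1)",4.6
6b,"3J(NH,H1)",9.8
7a,"3J(NH,H1)",5.0
7b,"3J(NH,H1)",8.6
8a,"3J(NH,H1)",7.7
8b,"3J(NH,H1)",nd
5a,"3J(15N,H2)",nd
5b,"3J(15N,H2)",2.1
6a,"3J(15N,H2)",0.5
6b,"3J(15N,H2)",1.0
7a,"3J(15N,H2)",1.8
7b,"3J(15N,H2)",2.0
8a,"3J(15N,H2)",1.7
8b,"3J(15N,H2)",1.3
5a,"1J(15N,C1)",10.9
5b,"1J(15N,C1)",13.1
6a,"1J(15N,C1)",11.2
6b,"1J(15N,C1)",12.7
7a,"1J(15N,C1)",11.8
7b,"1J(15N,C1)",13.1
8a,"1J(15N,C1)",12.5
8b,"1J(15N,C1)",12.1
5a,"2J(15N,C2)",1.3
5b,"2J(15N,C2)",1.3
6a,"2J(15N,C2)",3.5
6b,"2J(15N,C2)",0.9
7a,"2J(15N,C2)",1.2
7b,"2J(15N,C2)",1.2
8a,"2J(15N,C2)",1.7
8b,"2J(15N,C2)",b
5a,"3J(15N,C3)",0
5b,"3J(15N,C3)",2.3
6a,"3J(15N,C3)",0
6b,"3J(15N,C3)",2.2
7a,"3J(15N,C3)",b
7b,"3J(15N,C3)",2.3
8a,"3J(15N,C3)",1.3
8b,"3J(15N,C3)",b
5a,"3J(15N,C5)",1.1
5b,"3J(15N,C5)",1.4
6a,"3J(15N,C5)",0.8
6b,"3J(15N,C5)",1.2
7a,"3J(15N,C5)",b
7b,"3J(15N,C5)",1.6
8a,"3J(15N,C5)",1.0
8b,"3J(15N,C5)",b
5a,"1J(15N,Ci)",13.0
5b,"1J(15N,Ci)",13.7
6a,"1J(15N,Ci)",13.6
6b,"1J(15N,Ci)",13.9
7a,"1J(15N,Ci)",13.7
7b,"1J(15N,Ci)",13.7
8a,"1J(15N,Ci)",13.7
8b,"1J(15N,Ci)",14.0
5a,"2J(15N,Co)",2.3
5b,"2J(15N,Co)",2.3
6a,"2J(15N,Co)",2.3
6b,"2J(15N,Co)",2.1
7a,"2J(15N,Co)",2.3
7b,"2J(15N,Co)",2.3
8a,"2J(15N,Co)",2.3
8b,"2J(15N,Co)",2.3
5a,"3J(15N,Cm)",1.4
5b,"3J(15N,Cm)",1.4
6a,"3J(15N,Cm)",1.4
6b,"3J(15N,Cm)",1.3
7a,"3J(15N,Cm)",1.3
7b,"3J(15N,Cm)",1.3
8a,"3J(15N,Cm)",1.4
8b,"3J(15N,Cm)",1.4
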