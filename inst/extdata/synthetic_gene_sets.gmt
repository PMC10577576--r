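SYN_DEVELOPMENT	synthetic developmental transcription-factor set	GENE0001	GENE0002	GENE0003	GENE0004	GENE0005	GENE0006	GENE0007	GENE0008	GENE0009	GENE0010	GENE0011	GENE0012	GENE0013	GENE0014	GENE0015
SYN_ION_TRANSPORT	synthetic transmembrane ion-transport set	GENE0016	GENE0017	GENE0018	GENE0019	GENE0020	GENE0021	GENE0022	GENE0023	GENE0024	GENE0025
SYN_RANDOM_A	synthetic random control set	GENE0030	GENE0045	GENE0060	GENE0075	GENE0090	GENE0105	GENE0120	GENE0135	GENE0150	GENE0165
SYN_RANDOM_B	synthetic random control set	GENE0031	GENE0046	GENE0061	GENE0076	GENE0091	GENE0106	GENE0121	GENE0136	GENE0151	GENE0166
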