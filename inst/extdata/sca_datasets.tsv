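study_id	comparison_id	model	tissue	age	avg_read_depth	read_length	paired_end	is_short_repeat_control
GSE122099	GSE122099_82Q_cb_5w	ATXN1[82Q] Tg	Cerebellum	5 w	87537211		TRUE	FALSE
GSE122099	GSE122099_82Q_cb_12w	ATXN1[82Q] Tg	Cerebellum	12 w	92485001		TRUE	FALSE
GSE122099	GSE122099_82Q_io_5w	ATXN1[82Q] Tg	Inferior olive	5 w	99996263		TRUE	FALSE
GSE122099	GSE122099_82Q_io_12w	ATXN1[82Q] Tg	Inferior olive	12 w	97497000		TRUE	FALSE
GSE122099	GSE122099_154Q_cb_5w	Atxn1 154Q/2Q	Cerebellum	5 w	104290286		TRUE	FALSE
GSE122099	GSE122099_154Q_cb_12w	Atxn1 154Q/2Q	Cerebellum	12 w	115188043		TRUE	FALSE
GSE122099	GSE122099_154Q_io_5w	Atxn1 154Q/2Q	Inferior olive	5 w	87880555		TRUE	FALSE
GSE122099	GSE122099_154Q_io_12w	Atxn1 154Q/2Q	Inferior olive	12 w	99154063		TRUE	FALSE
GSE114674	GSE114674_aso_cb_18w	Atxn1 154Q/2Q, ASO treatment	Cerebellum	18 w	119643770		TRUE	FALSE
GSE114674	GSE114674_aso_pons_18w	Atxn1 154Q/2Q, ASO treatment	Pons	18 w	82569603		TRUE	FALSE
GSE114674	GSE114674_aso_med_18w	Atxn1 154Q/2Q, ASO treatment	Medulla	18 w	82934663		TRUE	FALSE
GSE114674	GSE114674_aso_pons_28w	Atxn1 154Q/2Q, ASO treatment	Pons	28 w	94023770		TRUE	FALSE
GSE114674	GSE114674_aso_med_28w	Atxn1 154Q/2Q, ASO treatment	Medulla	28 w	112181398		TRUE	FALSE
GSE108256	GSE108256_pcp2_cb_12w	Pcp2-ATXN1[82Q]	Cerebellum	12 w	114752434		TRUE	FALSE
GSE75778	GSE75778_30Q_cb_5w	ATXN1[30Q] Tg	Cerebellum	5 w	127380677		TRUE	TRUE
GSE75778	GSE75778_82Q_cb_5w	ATXN1[82Q] Tg	Cerebellum	5 w	130183849		TRUE	FALSE
GSE75778	GSE75778_82Q_cb_12w	ATXN1[82Q] Tg	Cerebellum	12 w	10182436		TRUE	FALSE
GSE75778	GSE75778_82Q_cb_28w	ATXN1[82Q] Tg	Cerebellum	28 w	9168448		TRUE	FALSE
GSE114815	GSE114815_pcp2_cb_9w	Pcp2-ATXN1[82Q]	Cerebellum	9 w	111934958		TRUE	FALSE
GSE114815	GSE114815_m120a_cb_9w	ATXN1[82Q];CaM120A/M120A	Cerebellum	9 w	118498910		TRUE	FALSE
GSE163885	GSE163885_154Q_cb_6w	Atxn1 154Q/2Q	Cerebellum	6 w	231979628		TRUE	FALSE
GSE163885	GSE163885_s776a_cb_6w	Atxn1 154Q[S776A]/2Q	Cerebellum	6 w	230593782		TRUE	FALSE
PRJEB24319	PRJEB24319_q127_cb_1d	ATXN2 Q127 Tg	Cerebellum	1 day	22095459		TRUE	FALSE
PRJEB24319	PRJEB24319_q127_cb_3w	ATXN2 Q127 Tg	Cerebellum	3 w	23312280		TRUE	FALSE
PRJEB24319	PRJEB24319_q127_cb_6w	ATXN2 Q127 Tg	Cerebellum	6 w	21850856		TRUE	FALSE
GSE107958	GSE107958_mjd_cb_17.5mo	MJD84.2	Cerebellum	17.5 mo	183848391		TRUE	FALSE
GSE107958	GSE107958_mjd_ctx_17.5mo	MJD84.2	Cortex	17.5 mo	175864178		TRUE	FALSE
GSE107958	GSE107958_mjd_str_17.5mo	MJD84.2	Striatum	17.5 mo	193332930		TRUE	FALSE
GSE107958	GSE107958_mjd_bs_17.5mo	MJD84.2	Brainstem	17.5 mo	68227029		TRUE	FALSE
GSE117605	GSE117605_yac15q_pons	YAC15Q hemi	Pons	22-24 w	51185663		TRUE	TRUE
GSE117605	GSE117605_yac84q_pons	YAC84Q hemi	Pons	22-24 w	56641310		TRUE	FALSE
GSE117605	GSE117605_kihet_pons	KI-het	Pons	22-24 w	4714289		TRUE	FALSE
GSE117605	GSE117605_kihom_pons	KI-hom	Pons	22-24 w	59753664		TRUE	FALSE
GSE145613	GSE145613_304Q_cb_2mo	304/304Q	Cerebellum	2 mo	47636024		TRUE	FALSE
GSE145613	GSE145613_304Q_cb_12mo	304/304Q	Cerebellum	12 mo	36060638		TRUE	FALSE
GSE178367	GSE178367_yac15q_cb_18mo	YAC15Q (no WT)	Cerebellum	18 mo	104531443		TRUE	TRUE
GSE178367	GSE178367_yac84q_igf1_cb_18mo	YAC84Q, IGF1 treatment	Cerebellum	18 mo	58606848		TRUE	FALSE
GSE138527	GSE138527_140Q_cb_40w	140Q/5Q	Cerebellum	40 w	43319128		FALSE	FALSE
GSE139090	GSE139090_92Q_cb_12w	SCA7 92Q	Cerebellum	12 w	33206832		TRUE	FALSE
GSE139090	GSE139090_92Q_cb_29w	SCA7 92Q	Cerebellum	29 w	34817416		TRUE	FALSE
GSE145067	GSE145067_tbp_cb_3mo	TBP-105Q	Cerebellum	3 mo	11548250		TRUE	FALSE
GSE145067	GSE145067_tbp_str_3mo	TBP-105Q	Striatum	3 mo	10299866		TRUE	FALSE
GSE145067	GSE145067_tbp_pfc_3mo	TBP-105Q	Prefrontal cortex	3 mo	9952160		TRUE	FALSE
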