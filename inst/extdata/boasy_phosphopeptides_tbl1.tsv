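# Phosphopeptides of the Brassica oleracea chromosome-axis proteins BoASY1
# and BoASY3 detected in anther (A) / meiocyte (M) co-IP experiments.
# One row per observed (possibly multiply phosphorylated) peptide form.
#   protein_positions: protein-level 1-based coordinates; ";" separates
#     co-occurring sites on a doubly phosphorylated peptide; "|" separates
#     the two candidate positions of one unresolved localization ambiguity.
#   pep_positions: the same sites in 1-based peptide coordinates.
#   probs: best site localization probabilities (percent), same separators.
protein_id	protein_positions	peptide_seq	pep_positions	probs	tissues
BoASY1	17	EAEITEQDSLLLTR	9	100.00	anther
BoASY1	253;260	STGPNSVHDEQPSDSDSEISQTK	6;13	97.33;99.82	meiocyte
BoASY1	260	STGPNSVHDEQPSDSDSEISQTK	13	99.99	anther;meiocyte
BoASY1	260;262	STGPNSVHDEQPSDSDSEISQTK	13;15	100.00;100.00	anther;meiocyte
BoASY1	262	STGPNSVHDEQPSDSDSEISQTK	15	99.85	anther;meiocyte
BoASY1	262;264	STGPNSVHDEQPSDSDSEISQTK	15;17	82.82;90.01	anther;meiocyte
BoASY1	294	ETQFLVAAVEKQEDDDGEVDEDNTQDPVESQQQLER	24	100.00	anther;meiocyte
BoASY1	294	QEDDDGEVDEDNTQDPVESQQQLER	13	100.00	anther;meiocyte
BoASY1	300	QEDDDGEVDEDNTQDPVESQQQLER	19	100.00	anther;meiocyte
BoASY1	294;300	QEDDDGEVDEDNTQDPVESQQQLER	13;19	100.00;100.00	anther;meiocyte
BoASY1	442|443	MVQEGYVEDSSNRR	10|11	50.00|50.00	anther
BoASY1	493	TNGQDAKLTPDVSTR	9	100.00	anther;meiocyte
BoASY1	493	LTPDVSTR	2	100.00	anther;meiocyte
BoASY1	504	GGIHSIGSDLTR	5	98.97	anther;meiocyte
BoASY1	504;507	GGIHSIGSDLTR	5;8	100.00;99.88	anther;meiocyte
BoASY1	507	GGIHSIGSDLTR	8	100.00	anther;meiocyte
BoASY1	526	SAMHQNGSVLSEQTISK	11	99.98	meiocyte
BoASY1	536	ANNTPMSSNAQPVASR	4	100.00	anther;meiocyte
BoASY1	539	ANNTPMSSNAQPVASR	7	99.39	anther;meiocyte
BoASY1	547|550	ANNTPMSSNAQPVASRESFAVK	15|18	50.00|50.00	meiocyte
BoASY1	568;569	ICTDAGTDSSQASQDRR	9;10	99.89;91.24	anther;meiocyte
BoASY1	569	ICTDAGTDSSQASQDR	10	96.10	anther;meiocyte
BoASY1	572	ICTDAGTDSSQASQDRR	13	98.72	anther;meiocyte
BoASY3	15	SFGSNFHPSSQPR	10	94.53	meiocyte
BoASY3	156	GNEMDKSPER	7	100.00	anther;meiocyte
BoASY3	205	ASPEYNEDVNSETPEVVK	2	99.67	meiocyte
BoASY3	231|232	LNQDKTSNDDPLTK	6|7	50.00|50.00	meiocyte
BoASY3	251|253	HHSDTIETDSESPEVATR	10|12	49.72|49.72	meiocyte
BoASY3	432;441	EKSVEPENDFQSPTFGYK	3;12	100.00;92.49	anther
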