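disease	n_disease	n_env	n_lifestyle	eli_printed
Obesity	210416	7892	15834	112.8
Type 2 diabetes	113333	2180	6477	76.4
Major depressive disorder	96868	3626	3466	73.2
Asthma	147762	9239	1152	70.3
Atopic dermatitis	19705	1100	144	63.1
Autism	28552	1437	98	53.8
Attention deficit hyperactivity disorder	25208	1160	164	52.5
Melanoma	98871	4546	237	48.4
Schizophrenia	112478	4004	949	44.0
Bipolar disorder	38944	1016	524	39.5
Coronary heart disease	262453	4267	5647	37.8
Psoriasis	37149	1208	167	37.0
Type 1 diabetes	68482	1561	875	35.6
Alzheimer's disease (late onset)	2958	56	35	30.8
Multiple sclerosis	63493	1565	331	29.9
Age-related macular degeneration	21515	506	111	28.7
Migraine	29512	569	264	28.2
Sudden cardiac arrest	25821	487	229	27.7
Breast cancer	292315	4727	2742	25.6
Migraine with aura	4446	89	23	25.2
Amyotrophic lateral sclerosis	18004	394	49	24.6
Amyotrophic lateral sclerosis (sporadic)	18004	394	49	24.6
Inflammatory bowel disease	74179	1425	351	23.9
Prostate cancer	123622	1855	1040	23.4
Colorectal cancer	172036	2470	1356	22.2
Crohn's disease	41342	732	178	22.0
Ulcerative colitis	36344	600	168	21.1
Parkinson's disease	76837	1368	248	21.0
Lung cancer	245974	4112	916	20.4
Myopia (pathological)	3990	77	2	19.8
Chronic kidney disease	117185	1281	961	19.1
Endometriosis	21212	342	59	18.9
Bladder cancer	62487	884	289	18.8
Systemic sclerosis	22938	387	36	18.4
Systemic lupus erythematosus	58576	929	110	17.7
Rheumatoid arthritis	120346	1578	393	16.4
Testicular germ cell tumor	27123	313	99	15.2
Ovarian cancer	86537	888	353	14.3
Graves' disease	18020	196	45	13.4
Celiac disease	20718	213	55	12.9
Acute lymphoblastic leukemia	32530	335	57	12.1
Chronic lymphocytic leukemia	19285	209	23	12.0
Pancreatic cancer	73158	622	172	10.9
Primary biliary cirrhosis	12347	93	25	9.6
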