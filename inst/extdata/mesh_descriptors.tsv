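dui	name	tree_numbers
D002446	Celiac Disease	C06.405.469.637.250
D003922	Diabetes Mellitus, Type 1	C18.452.394.750.124;C19.246.267;C20.111.327
D003874	Dermatitis Herpetiformis	C17.800.865.360;C20.111.290
D013967	Thyroiditis, Autoimmune	C19.874.871.102;C20.111.809
D001172	Arthritis, Rheumatoid	C05.550.114.154;C20.111.199
D008180	Lupus Erythematosus, Systemic	C17.300.480;C20.111.590
D009103	Multiple Sclerosis	C10.114.375.500;C20.111.258.250
D012859	Sjogren's Syndrome	C05.550.114.154.774;C20.111.199.774
D000224	Addison Disease	C19.053.500.263;C20.111.163
D001171	Arthritis, Juvenile	C05.550.114.125;C20.111.198
D019693	Hepatitis, Autoimmune	C06.552.380.350;C20.111.567
D006111	Graves' Disease	C19.874.397.370;C20.111.555
D005922	Glomerulonephritis, IGA	C12.777.419.570.363.304;C20.111.525
D009157	Myasthenia Gravis	C10.114.703.500;C20.111.258.500
D016884	Polyendocrinopathies, Autoimmune	C19.787;C20.111.736
D016736	Antiphospholipid Syndrome	C20.111.197
D900001	Iron Deficiency Anemia	C15.378.071.196
D900002	Osteoporosis	C05.116.198.579
D900003	Functional Dyspepsia	C06.405.117.119
D900004	Irritable Bowel Syndrome	C06.405.469.158.701
D900005	Lactose Intolerance	C18.452.603.476
D900006	Chronic Fatigue Syndrome	C10.228.140.380
D900007	Migraine Disorders	C10.228.140.546
D900008	Colorectal Neoplasms	C04.588.274.476
D900009	Intestinal Lymphoma	C04.557.386.480
D900010	Infertility	C13.351.500.894
D900011	Short Stature	C05.116.099.343
D900012	Aphthous Stomatitis	C07.465.864.750
D900013	Peripheral Neuropathy	C10.668.829
D900014	Ataxia	C10.597.350.090
D900015	Epilepsy	C10.228.140.490
D900016	Hyposplenism	C15.604.744
D900017	Pancreatitis	C06.689.750
D900018	Gastroesophageal Reflux	C06.405.117.367
D900019	Obesity	C18.654.726.500
D900020	Depressive Disorder	F03.600.300
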