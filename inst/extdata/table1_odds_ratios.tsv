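code	name	or	ci_low	ci_high
038	Septicemia	2.85	1.28	6.17
045	Acute poliomyelitis	inf	1.68	inf
138	Late effects of acute poliomyelitis	inf	6.10	inf
185	Malignant neoplasm of prostate	16.6	1.61	827.73
242	Thyrotoxicosis with or without goiter	3.35	1.26	8.64
276	Disorders of fluid electrolyte and acid-base balance	4	1.86	8.54
288	Diseases of white blood cells	16.6	1.61	827.73
290	Dementias	4.39	1.58	12.24
300	Anxiety, dissociative, and somatoform disorders	2	1.20	3.37
311	Depressive disorder, not elsewhere classified	3.23	1.16	8.71
323	Encephalitis myelitis and encephalomyelitis	inf	1.68	inf
331	Other cerebral degenerations	5.07	1.25	21.58
332	Parkinson's disease	18.35	4.78	103.91
333	Other extrapyramidal disease and abnormal movement disorders	4.44	1.67	11.78
336	Other diseases of spinal cord	24.93	5.28	236.30
343	Infantile cerebral palsy	8.48	1.77	53.57
344	Other paralytic syndromes	5.1	2.34	11.17
345	Epilepsy and recurrent seizures	3.29	1.01	10.30
348	Other conditions of brain	7.9	2.30	30.90
349	Other and unspecified disorders of the nervous system	3.66	1.85	7.18
351	Facial nerve disorders	6.98	1.33	45.92
352	Disorders of other cranial nerves	inf	2.70	inf
353	Nerve root and plexus disorders	5.4	2.97	9.83
354	Mononeuritis of upper limb and mononeuritis multiplex	3.33	1.76	6.23
355	Mononeuritis of lower limb and unspecified site	3.82	1.54	9.34
356	Hereditary and idiopathic peripheral neuropathy	15.36	6.77	37.64
357	Inflammatory and toxic neuropathy	6.82	2.92	16.47
358	Myoneural disorders	7.86	3.08	21.27
359	Muscular dystrophies and other myopathies	inf	16.82	inf
360	Disorders of the globe	4.93	1.51	16.50
427	Cardiac dysrhythmias	2.11	1.17	3.73
434	Occlusion of cerebral arteries	3.15	1.64	5.99
436	Acute, but ill-defined, cerebrovascular disease	5.06	2.28	11.32
438	Late effects of cerebrovascular disease	2.59	1.21	5.39
459	Other disorders of circulatory system	4.98	1.39	18.48
518	Other diseases of lung	6.28	2.73	14.81
590	Infections of kidney	2.75	1.01	7.14
714	Rheumatoid arthritis and other inflammatory polyarthropathies	2.49	1.10	5.42
718	Other derangement of joint	3.22	1.28	7.86
721	Spondylosis and allied disorders	2.35	1.40	3.99
722	Intervertebral disc disorders	2.18	1.28	3.71
728	Disorders of muscle ligament and fascia	2.49	1.46	4.23
729	Other disorders of soft tissues	3.59	1.70	8.47
758	Chromosomal anomalies	inf	1.68	inf
813	Fracture of radius and ulna	3.42	1.13	10.00
830	Dislocation of jaw	inf	1.68	inf
891	Open wound of knee, leg (except thigh), and ankle	2.18	1.08	4.29
952	Spinal cord injury without evidence of spinal bone injury	8.48	1.77	53.57
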