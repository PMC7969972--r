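wavelength_nm	mua_oxy_cm1	mua_deoxy_cm1	mel_ext_cm1_per_mg_ml
410.00000	552.0648469	319.765328	7.2419872
412.42424	568.7947480	366.963784	7.1150305
414.84848	575.8092055	414.596594	6.9910241
417.27273	572.8033120	461.116670	6.8698827
419.69697	560.0158194	504.850152	6.7515241
422.12121	538.2077916	544.095915	6.6358688
424.54545	508.5953485	577.237597	6.5228402
426.96970	472.7447516	602.858065	6.4123639
429.39394	432.4424002	619.845106	6.3043685
431.81818	389.5546901	627.477364	6.1987847
434.24242	345.8928905	625.481260	6.0955454
436.66667	303.0963089	614.052615	5.9945861
439.09091	262.5435252	593.840550	5.8958440
441.51515	225.2970541	565.895472	5.7992588
443.93939	192.0822194	531.586880	5.7047717
446.36364	163.2969861	492.499908	5.6123262
448.78788	139.0465075	450.321399	5.5218673
451.21212	119.1944783	406.726795	5.4333421
453.63636	103.4230299	363.278173	5.3466991
456.06061	91.2936736	321.341641	5.2618885
458.48485	82.3033449	282.029373	5.1788622
460.90909	75.9315297	246.168383	5.0975735
463.33333	71.6764233	214.295038	5.0179772
465.75758	69.0797784	186.671832	4.9400295
468.18182	67.7413963	163.321217	4.8636878
470.60606	67.3250280	144.070465	4.7889111
473.03030	67.5578137	128.601559	4.7156594
475.45455	68.2253881	116.500831	4.6438941
477.87879	69.1645279	107.304216	4.5735777
480.30303	70.2548314	100.535382	4.5046738
482.72727	71.4104955	95.735374	4.4371470
485.15152	72.5728754	92.483596	4.3709632
487.57576	73.7042089	90.410920	4.3060891
490.00000	74.7827205	89.206292	4.2424925
492.42424	75.7992980	88.618558	4.1801421
494.84848	76.7561013	88.455268	4.1190076
497.27273	77.6678422	88.580097	4.0590593
499.69697	78.5670392	88.910221	4.0002688
502.12121	79.5151642	89.414615	3.9426082
504.54545	80.6218834	90.113734	3.8860504
506.96970	82.0738778	91.080524	3.8305693
509.39394	84.1721091	92.442092	3.7761393
511.81818	87.3711359	94.380761	3.7227356
514.24242	92.3063514	97.132681	3.6703342
516.66667	99.7868033	100.981764	3.6189118
519.09091	110.7268891	106.246646	3.5684454
521.51515	125.9955432	113.258739	3.5189130
523.93939	146.1813051	122.330428	3.4702932
526.36364	171.3055428	133.714024	3.4225649
528.78788	200.5553155	147.554152	3.3757078
531.21212	232.1349497	163.838530	3.3297022
533.63636	263.3321354	182.354104	3.2845288
536.06061	290.8491688	202.656717	3.2401689
538.48485	311.3697873	224.062398	3.1966042
540.90909	322.2439179	245.666608	3.1538169
543.33333	322.1142648	266.394349	3.1117900
545.75758	311.3096595	285.079347	3.0705064
548.18182	291.8945228	300.565320	3.0299499
550.60606	267.3648937	311.817675	2.9901045
553.03030	242.0745354	318.030911	2.9509547
555.45455	220.5219482	318.716396	2.9124853
557.87879	206.6222429	313.757340	2.8746818
560.30303	203.0518554	303.422455	2.8375297
562.72727	210.7289804	288.336189	2.8010150
565.15152	228.5020288	269.410144	2.7651241
567.57576	253.1474212	247.746214	2.7298439
570.00000	279.7786410	224.525727	2.6951613
572.42424	302.6946924	200.900030	2.6610637
574.84848	316.5468626	177.896332	2.6275389
577.27273	317.5394404	156.348827	2.5945748
579.69697	304.2988990	136.860165	2.5621599
582.12121	278.1164853	119.793159	2.5302827
584.54545	242.4809460	105.288354	2.4989321
586.96970	202.0773586	93.300252	2.4680973
589.39394	161.6096529	83.643871	2.4377677
591.81818	124.8263457	76.043741	2.4079331
594.24242	93.9972123	70.179029	2.3785833
596.66667	69.8847278	65.720625	2.3497085
599.09091	52.0801781	62.358237	2.3212993
601.51515	39.4956318	59.817440	2.2933461
603.93939	30.8239438	57.867940	2.2658400
606.36364	24.8585047	56.325054	2.2387721
608.78788	20.6503327	55.046586	2.2121335
611.21212	17.5373867	53.927104	2.1859159
613.63636	15.1009929	52.891201	2.1601110
616.06061	13.0971852	51.886856	2.1347106
618.48485	11.3924363	50.879532	2.1097069
620.90909	9.9158506	49.847332	2.0850922
623.33333	8.6286935	48.777242	2.0608589
625.75758	7.5072486	47.662350	2.0369997
628.18182	6.5342080	46.499888	2.0135074
630.60606	5.6948277	45.289879	1.9903750
633.03030	4.9754478	44.034239	1.9675955
635.45455	4.3630587	42.736186	1.9451623
637.87879	3.8452721	41.399846	1.9230689
640.30303	3.4104124	40.029991	1.9013088
642.72727	3.0476203	38.631853	1.8798757
645.15152	2.7469309	37.210981	1.8587636
647.57576	2.4993167	35.773130	1.8379664
650.00000	2.2966984	34.324166	1.8174784
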