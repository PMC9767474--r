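id	lat	lon	age_bp	kind	gl0	gl1	gl2	genotype	allele
sim_0001	45.2094139645342	15.6107300200965	4093.7817373157	pseudohaploid	NA	NA	NA	NA	0
sim_0002	46.435955316294	11.8507976362016	3542.37154783054	pseudohaploid	NA	NA	NA	NA	0
sim_0003	46.0217237812467	9.11454454227351	4050.55374544568	pseudohaploid	NA	NA	NA	NA	0
sim_0004	50.5749884005636	3.891733313445	4076.21168128641	pseudohaploid	NA	NA	NA	NA	0
sim_0005	42.2300372819882	7.67909287847579	4817.62621956216	pseudohaploid	NA	NA	NA	NA	0
sim_0006	41.4281710975338	4.56994867068715	3839.38727922907	pseudohaploid	NA	NA	NA	NA	0
sim_0007	50.6490980640519	12.6375870150514	4633.83789115312	pseudohaploid	NA	NA	NA	NA	0
sim_0008	51.1080278058071	10.2917270094622	4561.91365216596	pseudohaploid	NA	NA	NA	NA	0
sim_0009	51.9582619573921	4.27764352457598	5681.26995587389	pseudohaploid	NA	NA	NA	NA	0
sim_0010	50.8928475822322	14.0831737346016	7200.9877043551	pseudohaploid	NA	NA	NA	NA	0
sim_0011	51.4195354888216	15.1966633398551	3793.40540009676	pseudohaploid	NA	NA	NA	NA	0
sim_0012	41.2169012813829	9.75726026669145	3501.67668175059	pseudohaploid	NA	NA	NA	NA	0
sim_0013	49.1595285593066	9.40255777374841	6649.33989172554	pseudohaploid	NA	NA	NA	NA	0
sim_0014	44.9601344591938	14.7531245686114	4339.27775576167	pseudohaploid	NA	NA	NA	NA	0
sim_0015	51.0956851195078	4.93813917017542	4993.87116336875	pseudohaploid	NA	NA	NA	NA	0
sim_0016	46.7275477859657	14.7909532391932	5022.82175462836	pseudohaploid	NA	NA	NA	NA	0
sim_0017	49.1591805119533	10.707493735943	4672.64031223621	pseudohaploid	NA	NA	NA	NA	0
sim_0018	51.5514367304277	11.0721524194814	7122.113182014	pseudohaploid	NA	NA	NA	NA	0
sim_0019	46.2860271122772	10.9412040724419	4525.31375689097	pseudohaploid	NA	NA	NA	NA	0
sim_0020	41.2093269256875	3.21849077404477	4989.90873032741	pseudohaploid	NA	NA	NA	NA	0
sim_0021	50.9601180665195	3.59857879416086	1530.27382694803	pseudohaploid	NA	NA	NA	NA	0
sim_0022	42.7346861767583	6.05830576270819	0.185162952176801	pseudohaploid	NA	NA	NA	NA	0
sim_0023	51.2919244614895	6.02485688612796	12.5465268809084	pseudohaploid	NA	NA	NA	NA	0
sim_0024	51.2381654190831	1.32887205970474	1.5116696891218	pseudohaploid	NA	NA	NA	NA	0
sim_0025	46.1953011215664	13.2092402528506	73.3297119438888	pseudohaploid	NA	NA	NA	NA	0
sim_0026	41.682097669458	5.41268270090222	1710.06443443883	pseudohaploid	NA	NA	NA	NA	0
sim_0027	46.5196577114984	9.30900061875582	24.0809656623539	pseudohaploid	NA	NA	NA	NA	0
sim_0028	44.4359741117805	6.94450396765023	21.512919321579	pseudohaploid	NA	NA	NA	NA	0
sim_0029	49.4207229013555	8.61986328987405	2669.53575950677	pseudohaploid	NA	NA	NA	NA	0
sim_0030	46.2660949141718	12.9816259862855	1012.22860215987	pseudohaploid	NA	NA	NA	NA	0
sim_0031	43.1348064467311	3.38621138967574	4.13447418426541	pseudohaploid	NA	NA	NA	NA	0
sim_0032	40.28179659741	4.98020720435306	2788.96787290158	pseudohaploid	NA	NA	NA	NA	0
sim_0033	47.5950627888087	10.9275403246284	44.8703643730386	pseudohaploid	NA	NA	NA	NA	0
sim_0034	43.5513782789931	13.9865356509108	1547.50837705112	pseudohaploid	NA	NA	NA	NA	0
sim_0035	42.6484405251686	4.80887428298593	0.0367549898833579	pseudohaploid	NA	NA	NA	NA	0
sim_0036	48.3691053485963	2.89287453121506	1288.74595468188	pseudohaploid	NA	NA	NA	NA	0
sim_0037	45.987141511403	10.1703061689623	754.678905038904	pseudohaploid	NA	NA	NA	NA	0
sim_0038	51.0295275917742	15.4398443289101	2167.5929551968	pseudohaploid	NA	NA	NA	NA	0
sim_0039	41.8847753719892	9.48736542998813	6.05830679480155	pseudohaploid	NA	NA	NA	NA	0
sim_0040	51.1272930421401	6.21140908217058	471.069466974105	pseudohaploid	NA	NA	NA	NA	0
sim_0001	48.2754838624969	13.0318881559651	0	diploid_genotype	NA	NA	NA	0	NA
sim_0002	41.2289039448369	10.1144675880205	0	diploid_genotype	NA	NA	NA	0	NA
sim_0003	43.014433905948	12.4689354759175	0	diploid_genotype	NA	NA	NA	0	NA
sim_0004	48.7289645625278	6.3969867376145	0	diploid_genotype	NA	NA	NA	0	NA
sim_0005	44.2498804717325	7.83361919410527	0	diploid_genotype	NA	NA	NA	0	NA
sim_0006	44.1611832766794	11.7611217433587	0	diploid_genotype	NA	NA	NA	0	NA
sim_0007	44.0170426501427	13.5733564489055	0	diploid_genotype	NA	NA	NA	0	NA
sim_0008	51.4861003451515	4.44750804593787	0	diploid_genotype	NA	NA	NA	0	NA
sim_0009	42.1029001718853	12.0838020080701	0	diploid_genotype	NA	NA	NA	0	NA
sim_0010	48.8015470046084	6.21913854731247	0	diploid_genotype	NA	NA	NA	0	NA
sim_0011	41.3543280649465	9.07557029183954	0	diploid_genotype	NA	NA	NA	0	NA
sim_0012	43.9364325392526	2.53442678437568	0	diploid_genotype	NA	NA	NA	0	NA
sim_0013	45.2458663922735	3.64135657669976	0	diploid_genotype	NA	NA	NA	0	NA
sim_0014	45.473141461378	14.525739317527	0	diploid_genotype	NA	NA	NA	0	NA
sim_0015	47.1915608712006	7.03928138804622	0	diploid_genotype	NA	NA	NA	0	NA
sim_0016	50.5832219698932	11.5458598397672	0	diploid_genotype	NA	NA	NA	0	NA
sim_0017	50.4594731898978	12.3727630972862	0	diploid_genotype	NA	NA	NA	0	NA
sim_0018	44.4674340479542	15.9613024145365	0	diploid_genotype	NA	NA	NA	0	NA
sim_0019	40.3998325555585	11.2573415690567	0	diploid_genotype	NA	NA	NA	0	NA
sim_0020	47.5052855962422	8.20795168331824	0	diploid_genotype	NA	NA	NA	1	NA
gl_1	45.2094139645342	15.6107300200965	4093.7817373157	genotype_likelihood	0.8902	0.0841	0.0257	NA	NA
gl_2	46.435955316294	11.8507976362016	3542.37154783054	genotype_likelihood	0.8944	0.0584	0.0472	NA	NA
gl_3	46.0217237812467	9.11454454227351	4050.55374544568	genotype_likelihood	0.9248	0.0128	0.0624	NA	NA
gl_4	50.5749884005636	3.891733313445	4076.21168128641	genotype_likelihood	0.8919	0.0421	0.0661	NA	NA
gl_5	42.2300372819882	7.67909287847579	4817.62621956216	genotype_likelihood	0.9326	0.024	0.0434	NA	NA
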