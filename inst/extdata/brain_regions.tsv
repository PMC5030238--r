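# Example brain-region dictionary: canonical name <TAB> acronyms <TAB> synonyms
# Lists are comma-separated; "-" marks an empty column.
PVT	-	paraventricular thalamus, paraventricular thalamic nucleus, paraventricular nucleus of the thalamus, paraventricular nucleus of thalamus
aPVT	-	anterior PVT, anterior paraventricular thalamic nucleus
pPVT	-	posterior PVT, posterior paraventricular thalamic nucleus
Pa	-	-
Pt	-	-
Amygdala	AMG	amygdaloid complex
Basal amygdala	BLA	-
Nucleus accumbens	NAS, NAc	accumbens nucleus, accumbens
Prefrontal cortex	PFC	-
Medial prefrontal cortex	mPFC	-
Suprachiasmatic nucleus	SCN	suprachiasmatic nuclei
Thalamus	-	-
Midline thalamus	-	-
Dorsal midline thalamus	-	-
Ventral subiculum	vSub	-
Hypothalamic orexin neurons	-	lateral hypothalamic orexin neurons, orexin neurons
Hypothalamus	-	-
Lateral septum	LS	-
Hippocampus	-	-
Locus coeruleus	LC	-
External lateral parabrachial subnucleus	elPB	-
Parabrachial nucleus	-	parabrachial nuclei, parabrachial
Paracentral nucleus	PC	paracentral thalamic nucleus, paracentral
Subthalamus	SbTh	subthalamic region, ventral thalamus
Parietal lobe	PL	parietal cortex, parietal region
Cingulate gyrus	CgG	cingular gyrus, cingulate area
Dorsal raphe	DR	caudal DR, caudal dorsal raphe
Basal forebrain	BF	-
Infralimbic cortex	IL	-
Bed nucleus of the stria terminalis	BNST	-
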