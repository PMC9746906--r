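stimulatory	synthetic placeholder checkpoint set	ICSTIM01	ICSTIM02	ICSTIM03	ICSTIM04	ICSTIM05	ICSTIM06	ICSTIM07	ICSTIM08	ICSTIM09	ICSTIM10	ICSTIM11	ICSTIM12	ICSTIM13	ICSTIM14	ICSTIM15
inhibitory	synthetic placeholder checkpoint set	ICINH01	ICINH02	ICINH03	ICINH04	ICINH05	ICINH06	ICINH07	ICINH08	ICINH09	ICINH10	ICINH11	ICINH12	ICINH13	ICINH14	ICINH15
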