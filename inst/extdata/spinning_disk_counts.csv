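condition,spherulites,small_aggregates
no_ligand,68,5
betaine_20mM,46,17
proline_20mM,42,16
betaine_100mM,55,49
proline_100mM,59,52
betaine_500mM,35,62
proline_500mM,38,58
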