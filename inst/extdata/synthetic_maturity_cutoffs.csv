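species,sex,cutoff_cm,source
scalloped_hammerhead,F,212,synthetic illustrative value
scalloped_hammerhead,M,156,synthetic illustrative value
great_hammerhead,F,228,synthetic illustrative value
great_hammerhead,M,225,synthetic illustrative value
tiger,F,287,synthetic illustrative value
tiger,M,292,synthetic illustrative value
white,F,450,synthetic illustrative value
white,M,360,synthetic illustrative value
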