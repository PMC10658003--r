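SPEAKER synthetic_example 1 2.086 1.550 <NA> <NA> D01A <NA> <NA>
SPEAKER synthetic_example 1 3.848 2.235 <NA> <NA> D01A <NA> <NA>
SPEAKER synthetic_example 1 6.420 1.571 <NA> <NA> D01A <NA> <NA>
SPEAKER synthetic_example 1 8.901 5.371 <NA> <NA> D01A <NA> <NA>
SPEAKER synthetic_example 1 16.983 0.368 <NA> <NA> D01A <NA> <NA>
SPEAKER synthetic_example 1 19.254 0.746 <NA> <NA> D01A <NA> <NA>
SPEAKER synthetic_example 1 0.641 1.394 <NA> <NA> D01B <NA> <NA>
SPEAKER synthetic_example 1 8.252 0.362 <NA> <NA> D01B <NA> <NA>
SPEAKER synthetic_example 1 15.491 1.222 <NA> <NA> D01B <NA> <NA>
SPEAKER synthetic_example 1 17.797 1.012 <NA> <NA> D01B <NA> <NA>
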