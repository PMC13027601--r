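wavelength_nm,n,k
354.24,0.1,1.419
367.91,0.07,1.657
381.49,0.05,1.864
397.39,0.05,2.07
413.28,0.05,2.275
430.5,0.04,2.462
450.85,0.04,2.657
471.42,0.05,2.869
495.94,0.05,3.093
520.94,0.05,3.324
548.6,0.06,3.586
582.09,0.05,3.858
616.84,0.06,4.152
659.49,0.05,4.483
704.46,0.04,4.838
756,0.03,5.242
821.09,0.04,5.727
891.97,0.04,6.312
984,0.04,6.992
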