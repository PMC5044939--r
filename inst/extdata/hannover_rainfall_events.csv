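event,year,month,observed_mm,normal_mm
wet_may,1981,5,108,56
wet_june,1981,6,146,65
wet_july,2002,7,171,67
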