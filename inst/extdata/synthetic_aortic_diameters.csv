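"age_days","site","diameter_cm"
1,"outflow tract",0.7
1,"sinuses of valsalva",0.9
1,"sinotubular junction",0.75
1,"tubular ascending aorta",0.65
30,"outflow tract",0.924
30,"sinuses of valsalva",1.305
30,"sinotubular junction",1.035
30,"tubular ascending aorta",1.0075
60,"outflow tract",0.7945
60,"sinuses of valsalva",1.2154
60,"sinotubular junction",0.948
60,"tubular ascending aorta",0.8844
150,"outflow tract",0.665
150,"sinuses of valsalva",1.1259
150,"sinotubular junction",0.861
150,"tubular ascending aorta",0.7612
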