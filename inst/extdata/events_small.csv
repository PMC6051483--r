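# n_rows=4
time_s,speed,direction_rad,window_start_s,window_end_s
               1.3,0.66495870960949843,0.78539816339744828,1.1200000000000001,               1.5
              1.76, 1.515193590747526,-0.78539816339744917,1.5600000000000001,              1.96
2.3199999999999998,0.76835520343967068,-0.78539816339744917,2.1200000000000001,              2.48
2.6400000000000001,0.95979895800672255,2.3561944901923448,              2.48,2.8199999999999998
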