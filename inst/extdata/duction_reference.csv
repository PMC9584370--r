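direction,degrees
elevation,40
depression,60
adduction,45
abduction,50
elevation_in_abduction,45
elevation_in_adduction,45
depression_in_abduction,55
depression_in_adduction,55
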