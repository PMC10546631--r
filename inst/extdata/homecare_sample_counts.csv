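variable,category,count
gender,men,18
gender,women,304
age,39y or less,49
age,40-54y,174
age,55y or more,99
place_of_birth,Spain,250
place_of_birth,Other,71
live_with_partner,No,104
live_with_partner,Yes,186
working_area_size,Rural,80
working_area_size,Intermediate,99
working_area_size,Urban,145
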