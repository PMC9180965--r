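pattern,scope,n_images,n_eyes
1:1:1,all,72,28
1:1:1,OS,41,15
1:1:1,OD,31,13
2:1,all,588,256
2:1,OS,294,129
2:1,OD,294,127
3:0,all,841,385
3:0,OS,406,190
3:0,OD,435,195
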