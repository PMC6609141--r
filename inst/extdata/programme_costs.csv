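"stage","component","label","amount"
1,"materials","Materials",6694
1,"training","Training",38079
2,"teaching","Teaching",27877
2,"facilitator","Facilitator (for parental component)",13250
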