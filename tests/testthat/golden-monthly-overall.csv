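month,drugs,tests,group,category,numerator,denominator,numerator_rounded,denominator_rounded,percentage
2020-01,azathioprine+leflunomide+methotrexate,all,,,5,32,5,30,16.7
2020-02,azathioprine+leflunomide+methotrexate,all,,,9,50,10,50,20
2020-03,azathioprine+leflunomide+methotrexate,all,,,14,48,15,50,30
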