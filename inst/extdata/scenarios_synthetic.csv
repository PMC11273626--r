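product,category,content,daily_amount,bw
synthetic_supplement_low,food_supplement,0.00102,10,60
synthetic_supplement_mid1,food_supplement,0.05,6,60
synthetic_supplement_mid2,food_supplement,0.3,12,60
synthetic_supplement_high,food_supplement,1.36,30,60
synthetic_herbal_low,herbal_medicine,0.01,3,60
synthetic_herbal_mid1,herbal_medicine,0.8,6,60
synthetic_herbal_mid2,herbal_medicine,4.5,9,60
synthetic_herbal_high,herbal_medicine,22.8,5,60
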