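"label","name","f_hz","sigma_S_per_m","eps_r"
1,"skin",50,0.1,9088
1,"skin",102.29,0.1,6816
1,"skin",209.27,0.1,5112
1,"skin",428.13,0.1,3862.4
1,"skin",875.89,0.1,2840
1,"skin",1791.93,0.1,2158.4
1,"skin",3665.99,0.1,1590.4
1,"skin",7500,0.1,1136
2,"skull",50,0.02,5900
2,"skull",102.29,0.02,4900
2,"skull",209.27,0.02,4100
2,"skull",428.13,0.02,3400
2,"skull",875.89,0.02,2800
2,"skull",1791.93,0.02,2400
2,"skull",3665.99,0.02,2000
2,"skull",7500,0.02,1700
3,"csf",50,1.79,109
3,"csf",102.29,1.79,109
3,"csf",209.27,1.79,109
3,"csf",428.13,1.79,109
3,"csf",875.89,1.79,109
3,"csf",1791.93,1.79,109
3,"csf",3665.99,1.79,109
3,"csf",7500,1.79,109
4,"grey_matter",50,0.075,4.1e+07
4,"grey_matter",102.29,0.078,1.9e+07
4,"grey_matter",209.27,0.082,8700000
4,"grey_matter",428.13,0.086,4e+06
4,"grey_matter",875.89,0.091,1800000
4,"grey_matter",1791.93,0.096,830000
4,"grey_matter",3665.99,0.102,380000
4,"grey_matter",7500,0.108,180000
5,"white_matter",50,0.053,2.9e+07
5,"white_matter",102.29,0.055,1.3e+07
5,"white_matter",209.27,0.058,5900000
5,"white_matter",428.13,0.06,2700000
5,"white_matter",875.89,0.063,1200000
5,"white_matter",1791.93,0.066,550000
5,"white_matter",3665.99,0.069,250000
5,"white_matter",7500,0.072,120000
6,"edema",50,1.7,4.1e+07
6,"edema",102.29,1.7,1.9e+07
6,"edema",209.27,1.7,8700000
6,"edema",428.13,1.7,4e+06
6,"edema",875.89,1.7,1800000
6,"edema",1791.93,1.7,830000
6,"edema",3665.99,1.7,380000
6,"edema",7500,1.7,180000
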