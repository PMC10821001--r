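exam_id,age_years,dlp_mgycm,ed_device_msv,sex
e001,0.25,310,3.57,F
e002,0.80,335,3.85,M
e003,2.50,600,4.56,M
e004,4.10,382,1.80,F
e005,7.00,412,1.94,M
e006,9.60,438,1.58,F
e007,12.40,465,1.67,M
e008,14.10,480,1.34,F
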