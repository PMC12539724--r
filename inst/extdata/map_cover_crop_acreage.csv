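year,government_acres,government_soc_published,voluntary_acres,voluntary_soc_published,total_acres,total_soc_published
2013,9617,5046,667655,350300,677272,355346
2014,18758,9842,421908,221363,440666,231205
2015,30364,15931,584722,306787,615086,322718
2016,23889,12534,537644,282087,561533,294621
2017,24386,12795,382446,200659,406832,213453
2018,94465,49563,785720,412245,880185,461808
2019,201361,105648,703263,368982,904624,474631
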