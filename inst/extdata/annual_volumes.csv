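fiscal_year,modality,total_exams,shared_exams,reported_proportion
2016,CT,287782,1507,0.524
2017,CT,298755,1665,0.557
2018,CT,304322,1580,0.519
2019,CT,307029,1774,0.578
2016,MRI,107876,537,0.498
2017,MRI,112018,560,0.500
2018,MRI,114528,574,0.501
2019,MRI,115929,612,0.528
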