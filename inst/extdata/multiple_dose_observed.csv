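study_id,dose_label,regimen,parameter,predicted,observed
karino,4.5,"4.5 mg (4)",auc_0_168,98878,103000
karino,4.5,"4.5 mg (4)",cmax,717.5,884.0
karino,4.5,"4.5 mg (4)",t_half,128.3,132.0
karino,4.5,"4.5 mg (4)",tmax,42.0,24.2
karino,5-5-8-10,"5 mg (2), 8 mg (1), 10 mg (1)",auc_0_168,189535,198000
karino,5-5-8-10,"5 mg (2), 8 mg (1), 10 mg (1)",cmax,1378.0,1510.0
karino,5-5-8-10,"5 mg (2), 8 mg (1), 10 mg (1)",t_half,128.3,126.0
karino,5-5-8-10,"5 mg (2), 8 mg (1), 10 mg (1)",tmax,45.3,24.2
furihata,5,"5 mg (8)",auc_0_168,112988,104000
furihata,5,"5 mg (8)",cmax,819.8,838.0
furihata,5,"5 mg (8)",t_half,128.3,127.0
furihata,5,"5 mg (8)",tmax,41.2,48.0
furihata,10,"2.5 mg (2), 5 mg (2), 10 mg (4)",auc_0_168,222479,192000
furihata,10,"2.5 mg (2), 5 mg (2), 10 mg (4)",cmax,1614.2,1520.0
furihata,10,"2.5 mg (2), 5 mg (2), 10 mg (4)",t_half,128.3,135.0
furihata,10,"2.5 mg (2), 5 mg (2), 10 mg (4)",tmax,41.0,24.0
furihata,15,"5 mg (2), 10 mg (4), 15 mg (2)",auc_0_168,318900,285000
furihata,15,"5 mg (2), 10 mg (4), 15 mg (2)",cmax,2314.5,2270.0
furihata,15,"5 mg (2), 10 mg (4), 15 mg (2)",t_half,128.3,121.0
furihata,15,"5 mg (2), 10 mg (4), 15 mg (2)",tmax,42.7,48.0
study_5,5,"2.5 mg (4), 5 mg (4)",auc_0_168,108794,110000
study_5,5,"2.5 mg (4), 5 mg (4)",cmax,789.5,915.0
study_5,5,"2.5 mg (4), 5 mg (4)",t_half,130.6,124.0
study_5,5,"2.5 mg (4), 5 mg (4)",tmax,42.0,24.0
study_5,10,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4)",auc_0_168,221867,263000
study_5,10,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4)",cmax,1609.9,2200.0
study_5,10,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4)",t_half,128.4,132.0
study_5,10,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4)",tmax,41.8,24.0
study_5,15,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4), 12.5 mg (4), 15 mg (4)",auc_0_168,336231.5,357000
study_5,15,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4), 12.5 mg (4), 15 mg (4)",cmax,2439.7,2930
study_5,15,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4), 12.5 mg (4), 15 mg (4)",t_half,128.25,126
study_5,15,"2.5 mg (4), 5 mg (4), 7.5 mg (4), 10 mg (4), 12.5 mg (4), 15 mg (4)",tmax,41.5,24
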