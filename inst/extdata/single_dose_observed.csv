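study_id,dose_mg,parameter,auc_window,predicted,observed
karino,2.5,auc,0_inf,56546,53200
karino,2.5,cmax,,228.1,231.0
karino,2.5,t_half,,128.3,120.0
karino,2.5,tmax,,54.7,24.0
karino,2.5,cl_over_f,,0.0440,0.0470
karino,5,auc,0_inf,113085,90500
karino,5,cmax,,494.2,397.0
karino,5,t_half,,128.0,123.0
karino,5,tmax,,40.0,24.1
karino,5,cl_over_f,,0.0442,0.0553
karino,8,auc,0_inf,223391,169000
karino,8,cmax,,901.4,874.0
karino,8,t_half,,128.3,111.0
karino,8,tmax,,54.7,48.0
karino,8,cl_over_f,,0.0358,0.0472
furihata,5,auc,0_168,113085,104000
furihata,5,cmax,,494.2,364.0
furihata,5,t_half,,128.0,127.0
furihata,5,tmax,,40.0,48.0
furihata,5,cl_over_f,,NA,NA
urva,5,auc,0_inf,113084,80500
urva,5,cmax,,494.2,339.0
urva,5,t_half,,128.0,121.0
urva,5,tmax,,40.0,48.0
urva,5,cl_over_f,,0.0442,0.0621
study_4,5,auc,0_inf,113084,84300
study_4,5,cmax,,494.2,510.0
study_4,5,t_half,,128.0,124.0
study_4,5,tmax,,40.0,24.0
study_4,5,cl_over_f,,0.0442,0.0593
study_5,2.5,auc,0_168,30673,35100
study_5,2.5,cmax,,228.8,306.0
study_5,2.5,t_half,,128.3,139.0
study_5,2.5,tmax,,54.7,24.0
study_5,2.5,cl_over_f,,0.0441,0.0384
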