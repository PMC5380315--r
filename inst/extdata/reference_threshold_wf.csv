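model,arm,bound,threshold_pct,wf_printed
bach,nlst_ct,lower,0.5,199.0
bach,nlst_ct,upper,12.7,6.9
bach,nlst_cxr,lower,0.9,110.1
bach,nlst_cxr,upper,13.5,6.4
bach,plco_cxr,lower,0.3,332.3
bach,plco_cxr,upper,10.4,8.6
bach,plco_control,lower,0.2,499.0
bach,plco_control,upper,8.9,10.2
llp,nlst_ct,lower,1.8,54.6
llp,nlst_ct,upper,8.0,11.5
llp,nlst_cxr,lower,1.2,82.3
llp,nlst_cxr,upper,7.3,12.7
llp,plco_cxr,lower,0.4,249.0
llp,plco_cxr,upper,6.5,14.4
llp,plco_control,lower,0.4,249.0
llp,plco_control,upper,5.8,16.2
llp_simplified,nlst_ct,lower,1.9,51.6
llp_simplified,nlst_ct,upper,8.5,10.8
llp_simplified,nlst_cxr,lower,1.9,51.6
llp_simplified,nlst_cxr,upper,8.5,10.8
llp_simplified,plco_cxr,lower,0.4,249.0
llp_simplified,plco_cxr,upper,8.5,10.8
llp_simplified,plco_control,lower,0.3,332.3
llp_simplified,plco_control,upper,5.3,17.9
plcom2012,nlst_ct,lower,0.9,110.1
plcom2012,nlst_ct,upper,16.1,5.2
plcom2012,nlst_cxr,lower,0.1,999.0
plcom2012,nlst_cxr,upper,10.5,8.5
plcom2012,plco_cxr,lower,0.2,499.0
plcom2012,plco_cxr,upper,9.0,10.1
plcom2012,plco_control,lower,0.1,999.0
plcom2012,plco_control,upper,11.0,8.1
plcom2012_simplified,nlst_ct,lower,0.7,141.9
plcom2012_simplified,nlst_ct,upper,13.6,6.4
plcom2012_simplified,nlst_cxr,lower,0.7,141.9
plcom2012_simplified,nlst_cxr,upper,12.0,7.3
plcom2012_simplified,plco_cxr,lower,0.3,332.3
plcom2012_simplified,plco_cxr,upper,9.3,9.8
plcom2012_simplified,plco_control,lower,0.2,499.0
plcom2012_simplified,plco_control,upper,8.5,10.8
tsce_incidence,nlst_ct,lower,2.0,49.0
tsce_incidence,nlst_ct,upper,12.1,7.3
tsce_incidence,nlst_cxr,lower,1.1,89.9
tsce_incidence,nlst_cxr,upper,8.0,11.5
tsce_incidence,plco_cxr,lower,0.3,332.3
tsce_incidence,plco_cxr,upper,7.9,11.7
tsce_incidence,plco_control,lower,0.2,499.0
tsce_incidence,plco_control,upper,6.9,13.5
knoke,nlst_ct,lower,3.5,27.6
knoke,nlst_ct,upper,13.3,6.5
knoke,nlst_cxr,lower,2.8,34.7
knoke,nlst_cxr,upper,8.8,10.4
knoke,plco_cxr,lower,3.0,32.3
knoke,plco_cxr,upper,7.7,12.0
knoke,plco_control,lower,2.9,33.5
knoke,plco_control,upper,7.2,12.9
tsce_cps_death,nlst_ct,lower,3.4,28.4
tsce_cps_death,nlst_ct,upper,7.1,13.1
tsce_cps_death,nlst_cxr,lower,2.8,34.7
tsce_cps_death,nlst_cxr,upper,6.2,15.1
tsce_cps_death,plco_cxr,lower,2.8,34.7
tsce_cps_death,plco_cxr,upper,6.2,15.1
tsce_cps_death,plco_control,lower,2.8,34.7
tsce_cps_death,plco_control,upper,6.0,15.7
tsce_nhs_hpfs_death,nlst_ct,lower,2.7,36.0
tsce_nhs_hpfs_death,nlst_ct,upper,16.7,5.0
tsce_nhs_hpfs_death,nlst_cxr,lower,2.0,49.0
tsce_nhs_hpfs_death,nlst_cxr,upper,9.9,9.1
tsce_nhs_hpfs_death,plco_cxr,lower,0.2,499.0
tsce_nhs_hpfs_death,plco_cxr,upper,7.8,11.8
tsce_nhs_hpfs_death,plco_control,lower,2.3,42.5
tsce_nhs_hpfs_death,plco_control,upper,6.6,14.2
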