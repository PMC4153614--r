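species,metric,scenario,auc,delta_aicc
T. lineola,F_ST,distance,NA,0
T. lineola,F_ST,topography,0.76,0.21
T. lineola,F_ST,climate,0.81,0.23
T. lineola,F_ST,all,0.86,0.77
T. lineola,F_ST,land use change,0.68,0.81
T. lineola,F_ST,land use,0.67,0.86
T. acteon,F_ST,land use change,0.69,0
T. acteon,F_ST,land use,0.71,0.80
T. acteon,F_ST,distance,NA,6.58
T. acteon,F_ST,climate,0.79,6.83
T. acteon,F_ST,topography,0.79,7.26
T. acteon,F_ST,all,0.84,7.29
T. sylvestris,F_ST,all,0.85,0
T. sylvestris,F_ST,climate,0.78,1.65
T. sylvestris,F_ST,land use,0.66,7.26
T. sylvestris,F_ST,land use change,0.66,8.02
T. sylvestris,F_ST,distance,NA,9.75
T. sylvestris,F_ST,topography,0.78,10.81
T. lineola,D_est,distance,NA,0
T. lineola,D_est,climate,0.81,2.58
T. lineola,D_est,topography,0.76,2.75
T. lineola,D_est,land use change,0.68,3.09
T. lineola,D_est,all,0.86,3.37
T. lineola,D_est,land use,0.67,3.58
T. acteon,D_est,land use change,0.69,0
T. acteon,D_est,land use,0.71,0.12
T. acteon,D_est,climate,0.79,4.40
T. acteon,D_est,distance,NA,5.29
T. acteon,D_est,all,0.84,5.79
T. acteon,D_est,topography,0.79,5.85
T. sylvestris,D_est,climate,0.78,0
T. sylvestris,D_est,land use change,0.66,1.89
T. sylvestris,D_est,land use,0.66,1.96
T. sylvestris,D_est,distance,NA,2.57
T. sylvestris,D_est,all,0.85,4.44
T. sylvestris,D_est,topography,0.78,5.47
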