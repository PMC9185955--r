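# Published per-bed implementation cost (CHF) and time (h) breakdown for seven
# analytic units; "total" rows are the printed per-unit totals. Material time
# is not applicable and coded NA.
category,measure,NH1,NH2,NH3,NH4,NH5,NH6,NH7
preparatory_leadership_meetings,cost,56.5,12.55,45.27,39.4,19.96,68.47,14.07
meeting_all_nhs,cost,13.24,3.49,23.08,0,0,4.81,12.01
leadership_icn_meetings,cost,59.32,21.36,89.88,45.55,27.02,39.38,31.68
icn_training,cost,340.81,99.24,131.76,158.21,171.05,268.12,0
phone_calls,cost,31.46,10.38,21.62,24.81,13.16,19.25,26.08
internal_training_events,cost,89,173.32,48.82,28.79,41.46,271.53,164.95
administration,cost,196.97,217.75,72.41,64.34,266.89,67,339.03
travel,cost,19.27,28.66,37.5,49.79,30.54,18.91,18.12
material,cost,0,2.35,0,0,48.97,35.17,27.78
total,cost,806.57,569.1,470.34,410.89,619.05,792.64,633.72
preparatory_leadership_meetings,time,0.88,0.21,0.91,0.75,0.37,1.31,0.1
meeting_all_nhs,time,0.19,0.07,0.38,0,0,0.11,0.12
leadership_icn_meetings,time,0.91,0.4,1.8,0.89,0.49,0.72,0.31
icn_training,time,7.03,2.48,1.2,3.25,3.42,6.09,0
phone_calls,time,0.65,0.26,0.43,0.53,0.26,0.44,0.36
internal_training_events,time,1.84,4.23,0.98,0.61,0.75,5.95,0.8
administration,time,3.49,3.56,1.45,1.3,4.78,1.31,0.78
travel,time,0.31,0.46,1.07,0.65,1.16,0.34,1.38
material,time,NA,NA,NA,NA,NA,NA,NA
total,time,15.3,11.67,8.22,7.98,11.23,16.27,3.85
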