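label,kind,k1,n1,k2,n2,mean1,sd1,sn1,mean2,sd2,sn2,diff
logit_gt7,logistic,16,80,14,36,NA,NA,NA,NA,NA,NA,NA
logit_gt21,logistic,10,80,13,36,NA,NA,NA,NA,NA,NA,NA
logit_gt7_alaska,logistic,3,23,14,36,NA,NA,NA,NA,NA,NA,NA
logit_gt21_alaska,logistic,0,23,13,36,NA,NA,NA,NA,NA,NA,NA
days_gt7,anova,NA,NA,NA,NA,32.7,21.1,16,62.6,20.2,14,30.0
days_gt21,anova,NA,NA,NA,NA,44.7,17.5,10,65.9,16.7,13,21.2
arrival,anova,NA,NA,NA,NA,241.2,20.2,14,261.4,22.7,16,20.2
departure,anova,NA,NA,NA,NA,309.7,6.7,7,287.4,19.3,12,22.3
pct_locations,anova,NA,NA,NA,NA,22.9,25.7,35,11.1,15.6,75,11.8
post_den_departure,anova,NA,NA,NA,NA,98.5,15.8,13,87.8,26.7,13,NA
shelf_coverage,anova,NA,NA,NA,NA,29.4,9.1,10,11.1,3.7,6,18.3
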