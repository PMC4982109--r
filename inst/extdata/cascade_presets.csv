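preset,marginal,process,param,value
cascade_mvn_rs,normal,none,beta0,24.13
cascade_mvn_rs,normal,none,beta1,-1.36
cascade_mvn_rs,normal,none,U00,33.68
cascade_mvn_rs,normal,none,rho,-0.39
cascade_mvn_rs,normal,none,U11,1.62
cascade_mvn_rs,normal,none,sigma,2.76
cascade_mvn_expcor,normal,expcor,beta0,24.12
cascade_mvn_expcor,normal,expcor,beta1,-1.35
cascade_mvn_expcor,normal,expcor,U00,33.22
cascade_mvn_expcor,normal,expcor,rho,-0.38
cascade_mvn_expcor,normal,expcor,U11,1.54
cascade_mvn_expcor,normal,expcor,sigma,2.79
cascade_mvn_expcor,normal,expcor,gamma_range,0.03
cascade_mvn_bm,normal,bm,beta0,23.81
cascade_mvn_bm,normal,bm,beta1,-1.15
cascade_mvn_bm,normal,bm,U00,28.69
cascade_mvn_bm,normal,bm,rho,-1
cascade_mvn_bm,normal,bm,U11,0.20
cascade_mvn_bm,normal,bm,sigma,2.28
cascade_mvn_bm,normal,bm,kappa,7.00
cascade_mvn_fbm,normal,fbm,beta0,23.82
cascade_mvn_fbm,normal,fbm,beta1,-1.15
cascade_mvn_fbm,normal,fbm,U00,27.46
cascade_mvn_fbm,normal,fbm,rho,-0.59
cascade_mvn_fbm,normal,fbm,U11,0.58
cascade_mvn_fbm,normal,fbm,sigma,2.01
cascade_mvn_fbm,normal,fbm,kappa,9.32
cascade_mvn_fbm,normal,fbm,hurst,0.30
cascade_mvt_rs,t,none,beta0,23.77
cascade_mvt_rs,t,none,beta1,-1.27
cascade_mvt_rs,t,none,U00,23.82
cascade_mvt_rs,t,none,rho,-0.37
cascade_mvt_rs,t,none,U11,1.17
cascade_mvt_rs,t,none,sigma,2.25
cascade_mvt_rs,t,none,df,5.64
cascade_mvt_expcor,t,expcor,beta0,23.76
cascade_mvt_expcor,t,expcor,beta1,-1.23
cascade_mvt_expcor,t,expcor,U00,22.83
cascade_mvt_expcor,t,expcor,rho,-0.36
cascade_mvt_expcor,t,expcor,U11,1.01
cascade_mvt_expcor,t,expcor,sigma,2.32
cascade_mvt_expcor,t,expcor,gamma_range,0.07
cascade_mvt_expcor,t,expcor,df,5.34
cascade_mvt_bm,t,bm,beta0,23.57
cascade_mvt_bm,t,bm,beta1,-1.10
cascade_mvt_bm,t,bm,U00,20.3
cascade_mvt_bm,t,bm,rho,-1
cascade_mvt_bm,t,bm,U11,0.12
cascade_mvt_bm,t,bm,sigma,1.88
cascade_mvt_bm,t,bm,kappa,5.17
cascade_mvt_bm,t,bm,df,5.83
cascade_mvt_fbm,t,fbm,beta0,23.59
cascade_mvt_fbm,t,fbm,beta1,-1.11
cascade_mvt_fbm,t,fbm,U00,18.82
cascade_mvt_fbm,t,fbm,rho,-0.51
cascade_mvt_fbm,t,fbm,U11,0.49
cascade_mvt_fbm,t,fbm,sigma,1.45
cascade_mvt_fbm,t,fbm,kappa,8.02
cascade_mvt_fbm,t,fbm,hurst,0.23
cascade_mvt_fbm,t,fbm,df,5.76
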