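name,family,mean,sd,min,max,mode,units,description
IR_s,lognormal,67,30,10,200,,mg/d,incidental soil ingestion rate (adult farmer/resident)
IR_sd,lognormal,50,30,5,200,,mg/d,incidental sediment ingestion rate while swimming
IR_w,lognormal,2.0,0.7,0.5,4.5,,L/d,daily drinking-water ingestion rate
IR_v,lognormal,0.30,0.12,0.05,0.8,,kg/d,vegetable ingestion rate (fresh weight)
IR_a,lognormal,16,4,5,30,,m3/d,air inhalation rate
EF_ia,point,350,,,,,d/yr,exposure frequency for indoor/daily activities
EF_oa,point,225,,,,,d/yr,exposure frequency for outdoor activities
EF_sw,lognormal,35,25,3,150,,events/yr,swimming frequency
ET_sw,triangular,0.75,,0.25,1.5,0.5,h/event,water-contact time per swimming event
ED,lognormal,24,8,5,60,,yr,exposure duration
BW,lognormal,60,10,40,100,,kg,adult body weight
SA_o,lognormal,0.57,0.12,0.30,1.0,,m2,exposed skin surface area during outdoor activities
SA_sw,lognormal,1.6,0.2,1.2,2.2,,m2,whole-body skin surface area during swimming
AF_sa,lognormal,0.22,0.12,0.02,0.6,,mg/cm2,soil-to-skin adherence factor (farmers)
AF_sr,lognormal,0.12,0.07,0.01,0.4,,mg/cm2,soil-to-skin adherence factor (residents)
AF_sd,lognormal,0.33,0.25,0.03,1.2,,mg/cm2,sediment-to-skin adherence factor (swimmers)
theta_v,triangular,0.90,,0.82,0.96,0.92,unitless,vegetable water content (fresh weight basis)
theta_w,lognormal,0.30,0.05,0.15,0.45,,L/L,water-filled soil porosity
rho_b,lognormal,1.5,0.15,1.1,1.9,,g/cm3,dry soil bulk density
DF,lognormal,20,14,3,100,,unitless,leachate dilution factor during transport to the aquifer
PEF,point,1.36e9,,,,,m3/kg,particulate emission factor
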