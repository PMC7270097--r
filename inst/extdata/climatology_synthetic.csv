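# Synthetic monthly climatology for three Indian Ocean eco-regions
# (NAS = Northern Arabian Sea, SEAS = South Eastern Arabian Sea,
# BoB = Bay of Bengal), constructed to mirror the qualitative regimes of the
# regions: NAS unimodal SST (cool summer monsoon), high salinity, strong
# chlorophyll bloom; SEAS bimodal SST, summer hypoxia, intense upwelling
# bloom; BoB warm, fresh, stable and low-chlorophyll.
# Units: SST degC, SSS ppt, DO mg/L, CHL mg/m3.
region,variable,month,value
NAS,SST,1,25.0
NAS,SST,2,24.5
NAS,SST,3,25.5
NAS,SST,4,27.0
NAS,SST,5,28.0
NAS,SST,6,22.0
NAS,SST,7,20.5
NAS,SST,8,20.0
NAS,SST,9,21.5
NAS,SST,10,26.0
NAS,SST,11,26.5
NAS,SST,12,25.5
NAS,SSS,1,36.5
NAS,SSS,2,36.6
NAS,SSS,3,36.8
NAS,SSS,4,37.0
NAS,SSS,5,37.2
NAS,SSS,6,37.5
NAS,SSS,7,37.8
NAS,SSS,8,38.0
NAS,SSS,9,37.6
NAS,SSS,10,37.0
NAS,SSS,11,36.8
NAS,SSS,12,36.6
NAS,DO,1,4.0
NAS,DO,2,4.0
NAS,DO,3,3.8
NAS,DO,4,3.5
NAS,DO,5,3.0
NAS,DO,6,2.5
NAS,DO,7,2.0
NAS,DO,8,2.2
NAS,DO,9,2.5
NAS,DO,10,3.0
NAS,DO,11,3.5
NAS,DO,12,3.8
NAS,CHL,1,1.5
NAS,CHL,2,1.2
NAS,CHL,3,1.0
NAS,CHL,4,2.0
NAS,CHL,5,5.0
NAS,CHL,6,8.0
NAS,CHL,7,9.0
NAS,CHL,8,10.0
NAS,CHL,9,7.0
NAS,CHL,10,4.0
NAS,CHL,11,2.0
NAS,CHL,12,1.5
SEAS,SST,1,27.0
SEAS,SST,2,27.5
SEAS,SST,3,28.5
SEAS,SST,4,29.5
SEAS,SST,5,30.0
SEAS,SST,6,27.5
SEAS,SST,7,26.5
SEAS,SST,8,26.0
SEAS,SST,9,26.5
SEAS,SST,10,29.0
SEAS,SST,11,29.5
SEAS,SST,12,27.5
SEAS,SSS,1,34.5
SEAS,SSS,2,34.8
SEAS,SSS,3,35.0
SEAS,SSS,4,35.2
SEAS,SSS,5,35.0
SEAS,SSS,6,34.5
SEAS,SSS,7,34.0
SEAS,SSS,8,33.8
SEAS,SSS,9,34.0
SEAS,SSS,10,34.2
SEAS,SSS,11,33.8
SEAS,SSS,12,34.2
SEAS,DO,1,4.0
SEAS,DO,2,4.0
SEAS,DO,3,3.8
SEAS,DO,4,3.5
SEAS,DO,5,2.5
SEAS,DO,6,1.5
SEAS,DO,7,1.0
SEAS,DO,8,1.2
SEAS,DO,9,1.8
SEAS,DO,10,3.0
SEAS,DO,11,3.8
SEAS,DO,12,4.0
SEAS,CHL,1,1.5
SEAS,CHL,2,1.2
SEAS,CHL,3,1.0
SEAS,CHL,4,1.5
SEAS,CHL,5,3.0
SEAS,CHL,6,6.0
SEAS,CHL,7,10.0
SEAS,CHL,8,9.0
SEAS,CHL,9,5.0
SEAS,CHL,10,2.0
SEAS,CHL,11,1.5
SEAS,CHL,12,1.2
BoB,SST,1,28.0
BoB,SST,2,28.2
BoB,SST,3,29.0
BoB,SST,4,29.5
BoB,SST,5,30.0
BoB,SST,6,29.5
BoB,SST,7,29.0
BoB,SST,8,28.8
BoB,SST,9,29.0
BoB,SST,10,29.2
BoB,SST,11,28.5
BoB,SST,12,28.0
BoB,SSS,1,31.5
BoB,SSS,2,31.8
BoB,SSS,3,32.0
BoB,SSS,4,32.5
BoB,SSS,5,33.0
BoB,SSS,6,32.0
BoB,SSS,7,30.5
BoB,SSS,8,29.0
BoB,SSS,9,28.5
BoB,SSS,10,29.0
BoB,SSS,11,30.0
BoB,SSS,12,31.0
BoB,DO,1,4.5
BoB,DO,2,4.5
BoB,DO,3,4.3
BoB,DO,4,4.0
BoB,DO,5,3.8
BoB,DO,6,3.5
BoB,DO,7,3.2
BoB,DO,8,3.0
BoB,DO,9,3.3
BoB,DO,10,3.8
BoB,DO,11,4.2
BoB,DO,12,4.5
BoB,CHL,1,0.5
BoB,CHL,2,0.5
BoB,CHL,3,0.6
BoB,CHL,4,0.8
BoB,CHL,5,1.2
BoB,CHL,6,2.0
BoB,CHL,7,2.5
BoB,CHL,8,3.0
BoB,CHL,9,2.0
BoB,CHL,10,1.2
BoB,CHL,11,0.8
BoB,CHL,12,0.6
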