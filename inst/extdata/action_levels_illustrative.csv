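# Synthetic illustrative action-level table.  Jurisdiction labels and
# interior values are invented; the anchored endpoints are published
# regulatory facts: ethephon regulated by nine jurisdictions (six at the
# 0.002 ppm egg tolerance, two at 1 ppm, one zero tolerance with LOQ
# 0.005 ppm), dimethomorph spanning 0.1-60 ppm in five jurisdictions,
# azoxystrobin 0.01-40 ppm in seventeen, chlorantraniliprole 0.01-40 ppm
# in twelve.
jurisdiction,pesticide,class,product_type,action_level_ppm,loq_ppm
J01,ethephon,plant growth regulator,any,0.002,
J02,ethephon,plant growth regulator,any,0.002,
J03,ethephon,plant growth regulator,any,0.002,
J04,ethephon,plant growth regulator,any,0.002,
J05,ethephon,plant growth regulator,any,0.002,
J06,ethephon,plant growth regulator,any,0.002,
J07,ethephon,plant growth regulator,any,1,
J08,ethephon,plant growth regulator,any,1,
J09,ethephon,plant growth regulator,any,0,0.005
J01,dimethomorph,fungicide,any,0.1,
J03,dimethomorph,fungicide,any,1,
J05,dimethomorph,fungicide,any,3,
J07,dimethomorph,fungicide,any,20,
J09,dimethomorph,fungicide,any,60,
J01,azoxystrobin,fungicide,any,0.01,
J02,azoxystrobin,fungicide,any,0.04,
J03,azoxystrobin,fungicide,any,0.1,
J04,azoxystrobin,fungicide,any,0.1,
J05,azoxystrobin,fungicide,any,0.1,
J06,azoxystrobin,fungicide,any,0.2,
J07,azoxystrobin,fungicide,any,0.2,
J08,azoxystrobin,fungicide,any,0.2,
J09,azoxystrobin,fungicide,any,0.2,
J10,azoxystrobin,fungicide,any,0.5,
J11,azoxystrobin,fungicide,any,0.5,
J12,azoxystrobin,fungicide,any,1,
J13,azoxystrobin,fungicide,any,1,
J14,azoxystrobin,fungicide,any,2,
J15,azoxystrobin,fungicide,any,5,
J16,azoxystrobin,fungicide,any,10,
J17,azoxystrobin,fungicide,any,40,
J01,chlorantraniliprole,insecticide,any,0.01,
J02,chlorantraniliprole,insecticide,any,0.1,
J03,chlorantraniliprole,insecticide,any,0.2,
J04,chlorantraniliprole,insecticide,any,0.2,
J05,chlorantraniliprole,insecticide,any,0.2,
J06,chlorantraniliprole,insecticide,any,0.5,
J07,chlorantraniliprole,insecticide,any,0.5,
J08,chlorantraniliprole,insecticide,any,1,
J09,chlorantraniliprole,insecticide,any,1,
J10,chlorantraniliprole,insecticide,any,2,
J11,chlorantraniliprole,insecticide,any,10,
J12,chlorantraniliprole,insecticide,any,40,
J10,abamectin,insecticide,any,0.1,
J11,abamectin,insecticide,any,0.1,
J12,abamectin,insecticide,any,0.2,
J13,abamectin,insecticide,any,0.3,
J14,abamectin,insecticide,any,0.5,
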