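name,observable,event,y,units,temperature_C,shape,weight
age_at_birth_21C,age_event,birth,2.0,d,21,alive,1
time_since_birth_at_puberty_21C,age_event,puberty,7.0,d,21,alive,1
time_since_birth_at_pupation_21C,age_event,pupation,15.0,d,21,alive,1
time_since_birth_at_pupation_15C,age_event,pupation,25.0,d,15,alive,1
time_at_emergence_20C,age_event,emergence,19.3,d,20,alive,1
length_at_birth,length,birth,0.09,cm,21,alive,1
length_at_pupation,length,pupation,1.38,cm,21,dead,1
initial_egg_dry_weight,dry_weight,egg,0.00099,mg,21,alive,1
wet_weight_at_pupation,wet_weight,pupation,10,mg,21,alive,1
imago_dry_weight,dry_weight,emergence,1.1,mg,21,alive,1
duration_instar_1_21C,instar_duration,molt1,2.0,d,21,alive,1
duration_instar_2_21C,instar_duration,molt2,2.0,d,21,alive,1
duration_instar_3_21C,instar_duration,puberty,3.0,d,21,alive,1
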