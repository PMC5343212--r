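label,arm,category,timing,basis,quantity,quantity_12mo,rate_ref,unit_price,life_years,use_years,scaling_role
Training,intervention,personnel_training,one_time,hours,9.9,,trainer,,,,fixed
Intervention delivery,intervention,personnel_delivery,per_phase,hours,183.7,261.7,research_associate,,,,variable
Website maintenance,intervention,website_maintenance,per_phase,hours,8.74,15.86,research_associate,,,,variable
Website hosting,intervention,website_hosting,recurring_monthly,unit,1,,,75,,,fixed
Technical support,intervention,website_technical_support,recurring_monthly,unit,2,,,95,,,fixed
Computer,intervention,hardware,one_time,purchase,1,,,700,5,3,fixed
Printer,intervention,hardware,one_time,purchase,1,,,400,5,3,fixed
Pedometers,intervention,materials,one_time,unit,104,,,12.50,,,variable
"Paper, ink, binders",intervention,materials,one_time,unit,1,,,597,,,variable
Video library,intervention,materials,one_time,unit,15,,,10,,,variable
Training,control,personnel_training,one_time,hours,3.3,,trainer,,,,fixed
Intervention delivery,control,personnel_delivery,per_phase,hours,63.97,100.98,research_associate,,,,variable
Website maintenance,control,website_maintenance,per_phase,hours,0.26,0.32,research_associate,,,,variable
Website hosting,control,website_hosting,recurring_monthly,unit,1,,,75,,,fixed
Technical support,control,website_technical_support,recurring_monthly,unit,2,,,95,,,fixed
Computer,control,hardware,one_time,purchase,1,,,700,5,3,fixed
Printer,control,hardware,one_time,purchase,1,,,400,5,3,fixed
"Paper, ink, binders",control,materials,one_time,unit,1,,,510,,,variable
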