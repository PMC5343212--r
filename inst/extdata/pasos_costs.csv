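label,arm,category,timing,amount_6mo,amount_12mo,scaling_role
Training,intervention,personnel_training,one_time,471,471,fixed
Intervention delivery,intervention,personnel_delivery,per_phase,5674,8083,variable
Website maintenance,intervention,website_maintenance,per_phase,270,490,variable
Website hosting,intervention,website_hosting,recurring_monthly,450,900,fixed
Technical support,intervention,website_technical_support,recurring_monthly,1140,2280,fixed
Computer,intervention,hardware,one_time,420,420,fixed
Printer,intervention,hardware,one_time,240,240,fixed
Pedometers,intervention,materials,one_time,1300,1300,variable
"Paper, ink, binders",intervention,materials,one_time,597,597,variable
Video library,intervention,materials,one_time,150,150,variable
Training,control,personnel_training,one_time,157,157,fixed
Intervention delivery,control,personnel_delivery,per_phase,1976,3119,variable
Website maintenance,control,website_maintenance,per_phase,8,10,variable
Website hosting,control,website_hosting,recurring_monthly,450,900,fixed
Technical support,control,website_technical_support,recurring_monthly,1140,2280,fixed
Computer,control,hardware,one_time,420,420,fixed
Printer,control,hardware,one_time,240,240,fixed
"Paper, ink, binders",control,materials,one_time,510,510,variable
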