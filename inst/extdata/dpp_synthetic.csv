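"disease","age_bucket","gender","dpp"
"IHD",1,"M",0.26
"IHD",2,"M",0.45
"IHD",3,"M",0.83
"IHD",4,"M",0.78
"IHD",5,"M",0.74
"IHD",6,"M",0.7
"IHD",7,"M",0.65
"IHD",1,"F",0.24
"IHD",2,"F",0.3
"IHD",3,"F",0.38
"IHD",4,"F",0.48
"IHD",5,"F",0.6
"IHD",6,"F",0.72
"IHD",7,"F",0.83
"Diabetes",1,"M",0.08
"Diabetes",2,"M",0.1
"Diabetes",3,"M",0.13
"Diabetes",4,"M",0.17
"Diabetes",5,"M",0.2
"Diabetes",6,"M",0.24
"Diabetes",7,"M",0.27
"Diabetes",1,"F",0.09
"Diabetes",2,"F",0.11
"Diabetes",3,"F",0.14
"Diabetes",4,"F",0.18
"Diabetes",5,"F",0.21
"Diabetes",6,"F",0.25
"Diabetes",7,"F",0.27
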