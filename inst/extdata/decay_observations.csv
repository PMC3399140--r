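species,temperature_C,k_per_day,exposure,source
Chum salmon,-0.5,-0.0018,Air,Study A
Rainbow trout,4.2,-0.0155,Water,Study B
Chum salmon,4.3,-0.0314,Air,Study A
Rainbow trout,4.4,-0.0210,Water,Study C
Chum salmon,8.0,-0.0236,Water,Study A
Chum salmon,8.0,-0.0358,Water,Study A
Rainbow trout,8.6,-0.0479,Water,Study B
Pink salmon,9.5,-0.0330,Water,Study D
Rainbow trout,16.0,-0.0570,Water,Study E
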