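{"samples":[8.73044386878989,26.1487977614221,43.4397573398286,60.5190827870246,77.3035653462392,93.711432705614,109.662747384687,125.079796181763,139.887468784819,154.013623701394,167.389439724691,179.949751223578,191.633365622989,202.383361528003,212.147366039156,220.877809907947,228.532159289425,235.073122962817,240.468834010602,244.69300507093,247.725056407009,249.550216169506,250.159592363526,249.550216169506,247.725056407011,244.693005070929,240.468834010604,235.073122962817,228.532159289424,220.877809907946,212.147366039156,202.383361528004,191.633365622987,179.949751223576,167.389439724692,154.013623701395,139.887468784821,125.079796181764,109.662747384688,93.7114327056128,77.3035653462392,60.5190827870231,43.4397573398291,26.1487977614217,8.73044386879054,-8.73044386879054,-26.1487977614217,-43.4397573398265,-60.5190827870258,-77.3035653462392,-93.7114327056128,-109.662747384688,-125.079796181764,-139.887468784819,-154.013623701393,-167.389439724692,-179.949751223578,-191.633365622991,-202.383361527999,-212.147366039158,-220.877809907946,-228.532159289426,-235.073122962817,-240.468834010603,-244.693005070931,-247.725056407006,-249.550216169511,-250.159592363524,-249.55021616951,-247.725056407005,-244.69300507093,-240.468834010602,-235.073122962817,-228.532159289426,-220.877809907947,-212.147366039157,-202.383361528,-191.633365622991,-179.949751223576,-167.389439724692,-154.013623701395,-139.887468784819,-125.079796181764,-109.662747384687,-93.7114327056131,-77.3035653462403,-60.519082787024,-43.4397573398288,-26.1487977614222,-8.73044386878998,-1.07502781221202e-28,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0,-0],"sampling_rate":204.8,"scaling":500,"provenance":"synthetic: one noise-free simulated stride (toe-off to toe-off), default gait profile, 204.8 Hz"}
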