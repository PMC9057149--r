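site,t1_s,t1_err_s,tau_c_s
C21,190,10,4.5e-4
C3,190,10,4.4e-4
C5,192,10,7.3e-4
C1,221,10,7.3e-4
C2,235,10,4.5e-4
C4,233,10,3.2e-4
C9,201,10,5e-5
C17,215,10,5e-6
C16,321,10,5e-5
C22,231,10,5.7e-5
C13,135,5,3e-5
C10,175,5,1.7e-5
C14,310,10,1e-4
C12,270,10,1e-5
C11,188,10,1.8e-5
C8,268,10,3.6e-5
C15,252,10,2.5e-5
C7,300,10,1.3e-5
C6,300,10,2.1e-5
C19,70,5,5.1e-6
C18,50,5,1.3e-6
C20,60,5,2.1e-6
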