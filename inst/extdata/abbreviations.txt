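e.g.
i.e.
etc.
vs.
cf.
ca.
approx.
fig.
figs.
al.
dr.
prof.
st.
no.
sp.
spp.
resp.
ref.
refs.
eq.
eqs.
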