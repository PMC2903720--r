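a
about
after
all
also
an
and
are
as
at
be
been
before
between
but
by
can
during
each
for
from
had
has
have
in
into
is
it
its
may
more
most
no
not
of
on
only
or
other
out
over
some
such
than
that
the
their
then
there
these
this
those
to
was
were
which
will
with
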